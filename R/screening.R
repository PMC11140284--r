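#' Pearson chi-square test of independence
#'
#' Uncorrected Pearson statistic `sum (O - E)^2 / E` on an R x C count
#' table, with `E = row total * column total / n`. No continuity
#' correction is applied, matching the convention of epidemiological
#' baseline tables.
#'
#' @param observed matrix (or table) of non-negative counts, at least 2 x 2.
#' @return List with `statistic`, `df = (R-1)(C-1)` and `p_value`.
#' @export
chi_square_test <- function(observed) {
  observed <- as.matrix(observed)
  if (nrow(observed) < 2L || ncol(observed) < 2L)
    stop("need at least 2 rows and 2 columns", call. = FALSE)
  if (any(observed < 0)) stop("counts must be non-negative", call. = FALSE)
  rs <- rowSums(observed); cs <- colSums(observed)
  if (any(rs == 0))
    stop("zero row margin for category ",
         paste(which(rs == 0), collapse = ", "), call. = FALSE)
  if (any(cs == 0))
    stop("zero column margin for category ",
         paste(which(cs == 0), collapse = ", "), call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(observed, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Mann-Whitney rank-sum test with tie-corrected normal approximation
#'
#' `U` is computed from midranks; the standardized statistic is
#' `Z = (U - n1 n2 / 2) / sigma_U` with the tie correction
#' `sigma_U^2 = n1 n2 / 12 * ((N + 1) - sum(t^3 - t) / (N (N - 1)))`,
#' and the two-sided p-value comes from the normal distribution (no
#' continuity correction).
#'
#' @param x,y numeric samples for the two groups (non-empty).
#' @return List with `U`, `Z`, `p_value`; `Z` and `p_value` are `NA` when
#'   all values are tied across both groups.
#' @export
mann_whitney_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y))
    stop("both groups must be non-empty", call. = FALSE)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  s2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (s2 <= 0) return(list(U = U, Z = NA_real_, p_value = NA_real_))
  Z <- (U - n1 * n2 / 2) / sqrt(s2)
  list(U = U, Z = Z, p_value = 2 * stats::pnorm(-abs(Z)))
}

#' Univariate screening of predictors against trajectory class
#'
#' Applies a chi-square test to each categorical or binary predictor
#' (class-by-level counts) and a Mann-Whitney test to each continuous
#' predictor, against the modal trajectory labels. Predictors with
#' `p < threshold` are flagged for the multivariable model.
#'
#' @param cohort cohort data frame (rows aligned with `labels`).
#' @param labels factor of class labels from [assign_labels()] (exactly two
#'   observed classes for continuous predictors).
#' @param predictors character vector of cohort column names; defaults to
#'   every generated predictor present.
#' @param threshold selection p-value threshold.
#' @return Data frame of class `screening_table`: one row per predictor
#'   with per-class summaries (count (%) or median (IQR)), the statistic,
#'   its kind, the p-value and the selection flag.
#' @export
screen_predictors <- function(cohort, labels, predictors = NULL,
                              threshold = 0.05) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L)
    stop("screening requires at least two observed classes", call. = FALSE)
  if (length(labels) != nrow(cohort))
    stop("labels must align with cohort rows", call. = FALSE)
  if (is.null(predictors))
    predictors <- intersect(names(default_predictor_specs()), names(cohort))
  rows <- lapply(predictors, function(nm) {
    v <- cohort[[nm]]
    if (is.null(v)) stop("unknown predictor '", nm, "'", call. = FALSE)
    if (is.numeric(v) && length(unique(v[!is.na(v)])) > 8L) {
      if (nlevels(labels) != 2L)
        stop("Mann-Whitney screening needs exactly two classes", call. = FALSE)
      g <- split(v, labels)
      ht <- mann_whitney_test(g[[1L]], g[[2L]])
      summ <- vapply(g, function(z)
        sprintf("%.1f (%.1f)", stats::median(z, na.rm = TRUE),
                stats::IQR(z, na.rm = TRUE)), "")
      data.frame(variable = nm, kind = "continuous",
                 t(stats::setNames(summ, paste0("class", seq_along(summ)))),
                 statistic = ht$Z, stat_kind = "Z", p_value = ht$p_value)
    } else {
      f <- as.factor(v)
      tab <- table(f, labels)
      ht <- chi_square_test(tab)
      summ <- vapply(seq_len(ncol(tab)), function(j)
        paste(sprintf("%s %d (%.1f%%)", rownames(tab), tab[, j],
                      100 * tab[, j] / sum(tab[, j])), collapse = "; "), "")
      data.frame(variable = nm, kind = "categorical",
                 t(stats::setNames(summ, paste0("class", seq_len(ncol(tab))))),
                 statistic = ht$statistic, stat_kind = "chi-square",
                 p_value = ht$p_value)
    }
  })
  out <- do.call(rbind, rows)
  out$selected <- !is.na(out$p_value) & out$p_value < threshold
  class(out) <- c("screening_table", class(out))
  attr(out, "threshold") <- threshold
  out
}
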