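#' Group summary statistics
#'
#' Mean, standard deviation and n for one group of cells, either computed
#' from samples or supplied directly from printed summary statistics.
#'
#' @param x Numeric samples, or `NULL` if `mean`, `sd`, `n` are given.
#' @param mean,sd,n Summary statistics (used when `x` is `NULL`).
#' @param label Group label (e.g. genotype x treatment).
#' @return List of class `group_summary`.
#' @export
group_summary <- function(x = NULL, mean = NULL, sd = NULL, n = NULL,
                          label = "") {
  if (!is.null(x)) {
    x <- x[!is.na(x)]
    out <- list(mean = base::mean(x), sd = stats::sd(x), n = length(x),
                label = label, samples = x)
  } else {
    if (is.null(mean) || is.null(sd) || is.null(n))
      stopf("group_summary: give samples or all of mean, sd, n")
    out <- list(mean = mean, sd = sd, n = n, label = label, samples = NULL)
  }
  if (out$n < 2) stopf("group_summary: n must be >= 2")
  if (out$sd < 0) stopf("group_summary: sd must be >= 0")
  structure(out, class = "group_summary")
}

#' Significance stars
#'
#' The per-comparison star convention: `***` for p < 0.001, `**` for
#' p < 0.01, `*` for p < 0.05, empty otherwise. No multiple-testing
#' correction is applied.
#'
#' @param p P value(s).
#' @return Character vector of stars.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_character_)
    if (pp < 0.001) "***" else if (pp < 0.01) "**" else if (pp < 0.05) "*"
    else ""
  }, character(1))
}

#' Two-tailed Student's t comparison of two groups
#'
#' Paired or unpaired two-tailed t-test. Unpaired tests default to the
#' Welch unequal-variance form (switchable to the classic pooled form);
#' summary-statistic input ([group_summary()] without samples) is allowed
#' only for unpaired tests. Paired tests require equal n in matched
#' order.
#'
#' @param a,b Numeric sample vectors or [group_summary()] objects.
#' @param paired Paired test?
#' @param var_equal Use the classic pooled-variance form instead of
#'   Welch (unpaired only).
#' @return List of class `comparison_result`: `t`, `df`, `p` (two-tailed),
#'   `kind` (`"paired"`/`"unpaired"`), `stars`, `mean_diff`.
#' @export
compare_groups <- function(a, b, paired = FALSE, var_equal = FALSE) {
  as_gs <- function(x) if (inherits(x, "group_summary")) x else
    group_summary(x = as.numeric(x))
  ga <- as_gs(a); gb <- as_gs(b)
  if (paired) {
    if (is.null(ga$samples) || is.null(gb$samples))
      stopf("compare_groups: paired test needs raw samples")
    if (ga$n != gb$n)
      stopf("compare_groups: paired test requires equal n (matched order)")
    d <- ga$samples - gb$samples
    n <- length(d)
    sdd <- sd(d)
    t_stat <- if (sdd == 0) {
      if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    } else mean(d) / (sdd / sqrt(n))
    df <- n - 1
  } else {
    m1 <- ga$mean; s1 <- ga$sd; n1 <- ga$n
    m2 <- gb$mean; s2 <- gb$sd; n2 <- gb$n
    if (var_equal) {
      sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
      df <- n1 + n2 - 2
    } else {
      v1 <- s1^2 / n1; v2 <- s2^2 / n2
      se <- sqrt(v1 + v2)
      df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    }
    if (se == 0) {
      # degenerate zero-variance groups: equal means are indistinguishable,
      # unequal means separate with certainty
      t_stat <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
      df <- n1 + n2 - 2
    } else {
      t_stat <- (m1 - m2) / se
    }
  }
  p <- if (t_stat == 0) 1 else if (is.infinite(t_stat)) 0 else
    2 * pt(-abs(t_stat), df)
  structure(list(t = t_stat, df = df, p = p,
                 kind = if (paired) "paired" else "unpaired",
                 stars = significance_stars(p),
                 mean_diff = ga$mean - gb$mean),
            class = "comparison_result")
}

#' Empirical CDF of particle ratios
#'
#' Nondecreasing step function from 0 to 1 over the sorted JC-1 ratios —
#' the membrane-potential distribution display used for genotype
#' comparison.
#'
#' @param ratios Numeric vector, length >= 1.
#' @return A `stats::ecdf` function.
#' @export
cdf_of_ratios <- function(ratios) {
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) == 0) stopf("cdf_of_ratios: no ratios supplied")
  ecdf(ratios)
}

#' Pearson correlation between particle size and membrane potential
#'
#' Product-moment correlation between per-particle lengths and JC-1
#' ratios; used to ask whether a mitochondrion's size predicts its
#' polarization.
#'
#' @param lengths,ratios Equal-length numeric vectors, n >= 3, both with
#'   nonzero variance.
#' @return Pearson r.
#' @export
size_ratio_correlation <- function(lengths, ratios) {
  ok <- !is.na(lengths) & !is.na(ratios)
  lengths <- lengths[ok]; ratios <- ratios[ok]
  if (length(lengths) != length(ratios))
    stopf("size_ratio_correlation: length mismatch")
  if (length(lengths) < 3) stopf("size_ratio_correlation: n must be >= 3")
  if (var(lengths) == 0 || var(ratios) == 0)
    stopf("size_ratio_correlation: constant input")
  cor(lengths, ratios)
}

#' Normalize drug effects to pretreatment baselines
#'
#' Each per-cell quantity after treatment is expressed relative to the
#' same cell before treatment (post/pre), so mitochondrial depolarization
#' appears as a normalized JC-1 ratio below 1. Cells are matched by id;
#' zero pretreatment values give `NA` with a flag.
#'
#' @param pre,post Data frames with a `cell_id` column and shared numeric
#'   columns.
#' @param id_col Name of the cell-identity column.
#' @return Data frame of post/pre quotients per cell, with a logical
#'   `undefined` column marking zero-pre entries.
#' @export
normalize_drug_effect <- function(pre, post, id_col = "cell_id") {
  if (!id_col %in% names(pre) || !id_col %in% names(post))
    stopf("normalize_drug_effect: missing '%s' column", id_col)
  if (!setequal(pre[[id_col]], post[[id_col]]) ||
      anyDuplicated(pre[[id_col]]) || anyDuplicated(post[[id_col]]))
    stopf("normalize_drug_effect: pre/post cells do not pair one-to-one")
  post <- post[match(pre[[id_col]], post[[id_col]]), , drop = FALSE]
  num <- setdiff(names(pre)[vapply(pre, is.numeric, TRUE)], id_col)
  num <- intersect(num, names(post))
  out <- data.frame(cell_id = pre[[id_col]])
  undef <- rep(FALSE, nrow(pre))
  for (v in num) {
    q <- post[[v]] / pre[[v]]
    bad <- !is.na(pre[[v]]) & pre[[v]] == 0
    q[bad] <- NA_real_
    undef <- undef | bad
    out[[v]] <- q
  }
  out$undefined <- undef
  names(out)[1] <- id_col
  out
}
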