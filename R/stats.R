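#' Summarize a condition sample
#'
#' Aggregates per-image tracing output into the per-condition quantities the
#' bridging analysis compares: molecule and junction counts (by type), the
#' percentage of molecules carrying at least one junction, and the mean +/-
#' SEM junction height difference. SEM uses the n-1 sample standard
#' deviation. The summary also carries the sufficient statistics (sum and sum
#' of squares of height differences) so that two summaries can be merged
#' exactly with [merge_summaries()].
#'
#' @param molecules Molecule table from [analyze_image()] (rows may be pooled
#'   across images).
#' @param junctions Junction table from [analyze_image()].
#' @param condition Condition label (e.g. `"dna"`, `"gapr"`).
#' @param density_class Density class label.
#' @return A `sample_summary` (list).
#' @export
summarize_sample <- function(molecules, junctions, condition = NA_character_,
                             density_class = NA_character_) {
  n_mol <- sum(molecules$est_n_molecules)
  if (nrow(molecules) == 0 || n_mol == 0)
    stop("cannot summarize a sample with zero molecules")
  jt <- factor(junctions$jtype, levels = c("intra", "inter", "ambiguous"))
  n_by_type <- table(jt)
  ## molecules displaying a junction, weighted by molecules per component
  with_j <- molecules$n_junctions > 0
  pct_with <- 100 * sum(molecules$est_n_molecules[with_j]) / n_mol
  has_intra <- molecules$component_id %in%
    junctions$component_id[junctions$jtype == "intra"]
  has_inter <- molecules$component_id %in%
    junctions$component_id[junctions$jtype == "inter"]
  pct_intra <- 100 * sum(molecules$est_n_molecules[has_intra]) / n_mol
  pct_inter <- 100 * sum(molecules$est_n_molecules[has_inter]) / n_mol
  hd <- junctions$height_diff_nm
  hd <- hd[is.finite(hd)]
  n_h <- length(hd)
  structure(list(
    condition = condition, density_class = density_class,
    n_molecules = n_mol,
    n_junctions = nrow(junctions),
    n_intra = as.integer(n_by_type[["intra"]]),
    n_inter = as.integer(n_by_type[["inter"]]),
    n_ambiguous = as.integer(n_by_type[["ambiguous"]]),
    pct_molecules_with_junction = pct_with,
    pct_intra = pct_intra, pct_inter = pct_inter,
    mean_height_diff = if (n_h > 0) mean(hd) else NA_real_,
    sem_height_diff = if (n_h > 1) stats::sd(hd) / sqrt(n_h) else NA_real_,
    n_height = n_h,
    sum_height = sum(hd), sumsq_height = sum(hd^2)),
    class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("<sample_summary> %s (%s density): %d molecules, %d junctions\n",
              x$condition, x$density_class, x$n_molecules, x$n_junctions))
  cat(sprintf("  %% molecules with junction: %.2f (intra %.2f, inter %.2f)\n",
              x$pct_molecules_with_junction, x$pct_intra, x$pct_inter))
  if (!is.na(x$mean_height_diff))
    cat(sprintf("  junction height difference: %.2f +/- %.2f nm (n = %d)\n",
                x$mean_height_diff, x$sem_height_diff, x$n_height))
  invisible(x)
}

#' Merge two sample summaries
#'
#' Exact pooled recomputation from sufficient statistics (counts add; the
#' pooled mean and SEM are recomputed, not averaged), so that summarizing two
#' halves and merging equals summarizing the whole.
#'
#' @param a,b `sample_summary` objects for the same condition.
#' @return A pooled `sample_summary`.
#' @export
merge_summaries <- function(a, b) {
  stopifnot(inherits(a, "sample_summary"), inherits(b, "sample_summary"))
  n_mol <- a$n_molecules + b$n_molecules
  wmean <- function(pa, pb) (pa * a$n_molecules + pb * b$n_molecules) / n_mol
  n_h <- a$n_height + b$n_height
  sh <- a$sum_height + b$sum_height
  sq <- a$sumsq_height + b$sumsq_height
  mean_h <- if (n_h > 0) sh / n_h else NA_real_
  sem_h <- if (n_h > 1) sqrt(max(0, (sq - sh^2 / n_h) / (n_h - 1))) / sqrt(n_h)
    else NA_real_
  structure(list(
    condition = a$condition, density_class = a$density_class,
    n_molecules = n_mol,
    n_junctions = a$n_junctions + b$n_junctions,
    n_intra = a$n_intra + b$n_intra,
    n_inter = a$n_inter + b$n_inter,
    n_ambiguous = a$n_ambiguous + b$n_ambiguous,
    pct_molecules_with_junction =
      wmean(a$pct_molecules_with_junction, b$pct_molecules_with_junction),
    pct_intra = wmean(a$pct_intra, b$pct_intra),
    pct_inter = wmean(a$pct_inter, b$pct_inter),
    mean_height_diff = mean_h, sem_height_diff = sem_h,
    n_height = n_h, sum_height = sh, sumsq_height = sq),
    class = "sample_summary")
}

#' Unpaired equal-variance Student's t test
#'
#' Classical pooled-variance two-sample t statistic with
#' `df = n_a + n_b - 2` and a two-sided p value. Degenerate inputs follow a
#' fixed contract: zero pooled variance with equal means gives `t = 0, p = 1`;
#' zero pooled variance with unequal means gives an infinite statistic and
#' `p = 0`, flagged in the result.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return List with `t`, `df`, `p`, and `degenerate` flag.
#' @export
unpaired_t_test <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each sample needs at least 2 values")
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  dm <- mean(a) - mean(b)
  if (sp2 <= 0) {
    if (dm == 0) return(list(t = 0, df = df, p = 1, degenerate = TRUE))
    return(list(t = sign(dm) * Inf, df = df, p = 0, degenerate = TRUE))
  }
  tt <- dm / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df), degenerate = FALSE)
}

#' Density-stratified fold changes in junction percentages
#'
#' Compares junction prevalence between a low-density and a high-density
#' sample of the same condition: the intermolecular fold change is the ratio
#' of inter-junction percentages high over low (bridging between molecules
#' rises with crowding), and the intramolecular fold change is low over high.
#' Zero denominators give `Inf` with a flag.
#'
#' @param summary_low,summary_high `sample_summary` objects.
#' @return List with `fold_inter`, `fold_intra`, `flagged`.
#' @export
density_fold_change <- function(summary_low, summary_high) {
  stopifnot(inherits(summary_low, "sample_summary"),
            inherits(summary_high, "sample_summary"))
  if (summary_low$n_molecules <= 0 || summary_high$n_molecules <= 0)
    stop("both summaries need molecule counts > 0")
  fi <- summary_high$pct_inter / summary_low$pct_inter
  fa <- summary_low$pct_intra / summary_high$pct_intra
  list(fold_inter = fi, fold_intra = fa,
       flagged = !is.finite(fi) || !is.finite(fa))
}
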