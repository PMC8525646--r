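#' ddPCR fractional abundance with Poisson correction
#'
#' Per-channel concentration from positive-droplet fractions,
#' \eqn{\lambda = -\ln(1 - p)/v} (copies/uL for droplet volume \eqn{v} in
#' uL), wild-type-allele fractional abundance
#' \eqn{FA = \lambda_{VIC} / (\lambda_{VIC} + \lambda_{FAM})} (VIC = WT
#' allele, FAM = variant allele), and normalization of each sample's FA to
#' the mean FA of the reference genotype. A purely wild-type sample
#' (\eqn{\lambda_{FAM} = 0}) therefore has FA exactly 1, and a balanced
#' heterozygote ~0.5 after normalization.
#'
#' @param samples data.frame with columns `sample_id`, `genotype`,
#'   `vic_pos`, `vic_total`, `fam_pos`, `fam_total`, `droplet_vol` (uL),
#'   e.g. from [gen_ddpcr_counts()].
#' @param reference_genotype genotype used as the normalization reference
#'   (default `"WT"`).
#' @return `samples` with added columns `lambda_vic`, `lambda_fam`
#'   (copies/uL), `fa` and `fa_normalized`.
#' @export
ddpcr_fractional_abundance <- function(samples, reference_genotype = "WT") {
  need <- c("vic_pos", "vic_total", "fam_pos", "fam_total", "droplet_vol")
  stopifnot(all(need %in% names(samples)))
  if (any(samples$vic_total <= 0 | samples$fam_total <= 0))
    stop("zero total droplets")
  p_vic <- samples$vic_pos / samples$vic_total
  p_fam <- samples$fam_pos / samples$fam_total
  if (any(p_vic >= 1 | p_fam >= 1))
    stop("channel saturated: all droplets positive, concentration undefined")
  samples$lambda_vic <- -log(1 - p_vic) / samples$droplet_vol
  samples$lambda_fam <- -log(1 - p_fam) / samples$droplet_vol
  tot <- samples$lambda_vic + samples$lambda_fam
  if (any(tot <= 0)) stop("no template detected in either channel")
  samples$fa <- samples$lambda_vic / tot
  ref <- samples$genotype == reference_genotype
  if (!any(ref)) stop("reference genotype absent: ", reference_genotype)
  samples$fa_normalized <- samples$fa / mean(samples$fa[ref])
  samples
}

#' Kyphotic index from spinal landmarks
#'
#' Ratio of the length of the chord drawn from the caudal margin of the
#' seventh cervical vertebra (C7) to the caudal margin of the sixth lumbar
#' vertebra (L6), to the perpendicular distance from the dorsal apex of the
#' spine to that chord. Lower values indicate more pronounced kyphosis. The
#' index is invariant under rigid rotation, translation and uniform scaling
#' of the landmark set.
#'
#' @param c7,l6,apex numeric length-2 coordinates (same units, e.g. image
#'   px or mm).
#' @return dimensionless index (chord / perpendicular).
#' @export
kyphotic_index <- function(c7, l6, apex) {
  stopifnot(length(c7) == 2, length(l6) == 2, length(apex) == 2)
  chord_vec <- l6 - c7
  chord <- sqrt(sum(chord_vec^2))
  if (chord <= 0) stop("C7 and L6 landmarks coincide")
  # perpendicular distance via the 2-D cross product
  ap <- apex - c7
  perp <- abs(chord_vec[1] * ap[2] - chord_vec[2] * ap[1]) / chord
  if (perp <= 1e-12 * chord)
    stop("landmarks are collinear: kyphotic index undefined (infinite)")
  chord / perp
}

#' Cohort summary table with optional group tests
#'
#' Group means with SEM (mean +/- SEM convention), and named standard tests
#' delegated to the host statistics routines: `"t"` ([stats::t.test]),
#' `"mann-whitney"` ([stats::wilcox.test]), `"kruskal"`
#' ([stats::kruskal.test]), `"anova"` ([stats::aov]).
#'
#' @param table data.frame of per-animal measurements.
#' @param value name of the measurement column.
#' @param group name of the grouping column (e.g. genotype).
#' @param tests character vector of test names to run (two-group tests
#'   require exactly two groups).
#' @param alternative passed to the two-group tests (default
#'   `"two.sided"`).
#' @return list with `summary` (data.frame `group`, `n`, `mean`, `sem`) and
#'   `tests` (data.frame `test`, `statistic`, `p_value`, `alternative`).
#' @export
cohort_summary <- function(table, value, group, tests = character(0),
                           alternative = "two.sided") {
  stopifnot(value %in% names(table), group %in% names(table))
  x <- table[[value]]; g <- factor(table[[group]])
  if (any(tabulate(g) == 0) || !length(x)) stop("empty group")
  sem <- function(v) sd(v) / sqrt(length(v))
  sm <- data.frame(group = levels(g),
                   n = as.integer(table(g)),
                   mean = as.numeric(tapply(x, g, mean)),
                   sem = as.numeric(tapply(x, g, sem)))
  res <- NULL
  for (tn in tests) {
    two <- nlevels(g) == 2
    out <- switch(tn,
      "t" = {
        if (!two) stop("t test requires exactly two groups")
        ht <- t.test(x ~ g, alternative = alternative)
        c(ht$statistic, ht$p.value)
      },
      "mann-whitney" = {
        if (!two) stop("Mann-Whitney requires exactly two groups")
        ht <- wilcox.test(x ~ g, alternative = alternative, exact = TRUE)
        c(ht$statistic, ht$p.value)
      },
      "kruskal" = { ht <- kruskal.test(x ~ g); c(ht$statistic, ht$p.value) },
      "anova" = {
        ht <- anova(aov(x ~ g))
        c(ht$`F value`[1], ht$`Pr(>F)`[1])
      },
      stop("unknown test: ", tn))
    res <- rbind(res, data.frame(test = tn, statistic = unname(out[1]),
                                 p_value = unname(out[2]),
                                 alternative = if (tn %in% c("t", "mann-whitney"))
                                   alternative else "two.sided"))
  }
  list(summary = sm, tests = res)
}
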