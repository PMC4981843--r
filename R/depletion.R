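# Depletion-outcome statistics from read-count tables and qPCR Ct tables.
#
# Count data live in a long tibble with columns sample, condition, gene,
# class, count ("count tibble"); classes partition the genes
# (globin_alpha / globin_beta / spikein / other). "Normalized read count"
# is the fraction of a sample's total counts — it reproduces every
# prevalence statement a depletion experiment needs without a UMI pipeline.

validate_count_tbl <- function(tbl) {
  need <- c("sample", "condition", "gene", "class", "count")
  if (!is.data.frame(tbl) || !all(need %in% names(tbl))) {
    abort(sprintf("Count tibble needs columns %s.", paste(need, collapse = ", ")))
  }
  if (any(tbl$count < 0)) abort("Counts must be non-negative.")
  cls <- distinct(tbl, .data$gene, .data$class)
  if (anyDuplicated(cls$gene)) {
    abort(sprintf("Gene '%s' has more than one class.",
                  cls$gene[duplicated(cls$gene)][1L]))
  }
  invisible(tbl)
}

#' Read a count matrix, gene annotation and sample sheet into a count tibble
#'
#' @param counts_path TSV with a `gene` column and one column per sample.
#' @param annot_path TSV with columns `gene`, `class`.
#' @param samples_path TSV with columns `sample`, `condition`.
#' @return A long count tibble (`sample`, `condition`, `gene`, `class`,
#'   `count`).
#' @export
read_counts <- function(counts_path, annot_path, samples_path) {
  counts <- as_tibble(read.delim(counts_path, check.names = FALSE,
                                 stringsAsFactors = FALSE))
  annot <- as_tibble(read.delim(annot_path, stringsAsFactors = FALSE))
  samples <- as_tibble(read.delim(samples_path, stringsAsFactors = FALSE))
  long <- tidyr::pivot_longer(counts, -"gene", names_to = "sample",
                              values_to = "count")
  out <- long |>
    left_join(annot, by = "gene") |>
    left_join(samples, by = "sample") |>
    select("sample", "condition", "gene", "class", "count")
  validate_count_tbl(out)
  out
}

#' Prevalence of a gene class within a sample
#'
#' The fraction of a sample's total read counts carried by genes of the
#' given class (or union of classes). Classes are disjoint, so prevalence
#' is additive over class unions: alpha- plus beta-globin prevalence is the
#' total globin prevalence.
#'
#' @param tbl A count tibble.
#' @param sample Sample id.
#' @param cls Character vector of class labels (a union is allowed, e.g.
#'   `c("globin_alpha", "globin_beta")`).
#'
#' @return A fraction in \[0, 1\].
#' @export
class_prevalence <- function(tbl, sample, cls) {
  validate_count_tbl(tbl)
  sub <- tbl[tbl$sample == sample, , drop = FALSE]
  if (nrow(sub) == 0L) abort(sprintf("Sample '%s' not found.", sample))
  total <- sum(sub$count)
  if (total == 0) abort(sprintf("Sample '%s' has zero total counts.", sample))
  sum(sub$count[sub$class %in% cls]) / total
}

#' Reduction fold change between control and treated prevalence
#'
#' @param p_control Prevalence without treatment (in (0, 1]).
#' @param p_treated Prevalence with treatment (>= 0).
#' @return `p_control / p_treated`. A zero treated prevalence yields `Inf`
#'   (complete depletion at the observed depth), flagged by its infiniteness
#'   rather than an error.
#' @export
#' @examples
#' reduction_fold(0.636, 0.052) # > 10
reduction_fold <- function(p_control, p_treated) {
  if (any(p_control <= 0 | p_control > 1)) abort("`p_control` must be in (0, 1].")
  if (any(p_treated < 0)) abort("`p_treated` must be >= 0.")
  ifelse(p_treated == 0, Inf, p_control / p_treated)
}

#' Spike-in count correlation between two samples
#'
#' Pearson correlation of transformed spike-in counts between two samples;
#' with no blocker binding sites on the spike-ins, this isolates technical
#' variation and measures blocker specificity.
#'
#' @param tbl A count tibble.
#' @param sample_a,sample_b Sample ids.
#' @param transform Count transform applied before correlating; default
#'   `log10(count + 1)`.
#' @return Pearson r.
#' @export
spikein_correlation <- function(tbl, sample_a, sample_b,
                                transform = function(x) log10(x + 1)) {
  validate_count_tbl(tbl)
  sp <- tbl[tbl$class == "spikein", , drop = FALSE]
  a <- sp[sp$sample == sample_a, c("gene", "count")]
  b <- sp[sp$sample == sample_b, c("gene", "count")]
  m <- merge(a, b, by = "gene", suffixes = c("_a", "_b"))
  if (nrow(m) < 3L) abort("Need at least 3 spike-in genes present in both samples.")
  cor(transform(m$count_a), transform(m$count_b), method = "pearson")
}

#' Gene detection sets for two conditions
#'
#' A gene is detected in a condition when its counts pooled over that
#' condition's samples reach `min_count`. Returns the genes detected in
#' both conditions and those unique to each.
#'
#' @param tbl A count tibble.
#' @param condition_a,condition_b Condition labels.
#' @param min_count Pooled-count detection threshold (default 1 read).
#' @return A list with character vectors `shared`, `only_a`, `only_b`.
#' @export
detection_sets <- function(tbl, condition_a, condition_b, min_count = 1) {
  validate_count_tbl(tbl)
  pooled <- tbl |>
    filter(.data$condition %in% c(condition_a, condition_b)) |>
    group_by(.data$condition, .data$gene) |>
    summarise(count = sum(.data$count), .groups = "drop")
  det <- function(cond) {
    pooled$gene[pooled$condition == cond & pooled$count >= min_count]
  }
  da <- det(condition_a); db <- det(condition_b)
  list(shared = intersect(da, db),
       only_a = setdiff(da, db),
       only_b = setdiff(db, da))
}

#' Wilson score interval for a binomial proportion
#'
#' @param x Successes.
#' @param n Trials.
#' @param conf Confidence level.
#' @return A two-column matrix (`low`, `high`).
#' @export
wilson_interval <- function(x, n, conf = 0.95) {
  if (any(n <= 0)) abort("`n` must be > 0.")
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  cbind(low = pmax(0, center - half), high = pmin(1, center + half))
}

#' Per-gene normalized counts with confidence intervals
#'
#' Each gene's fraction of the sample's total counts, with a Wilson score
#' 95% interval on the binomial proportion (well-behaved at zero counts).
#'
#' @param tbl A count tibble.
#' @param sample Sample id.
#' @param conf Confidence level.
#' @return A tibble: `gene`, `class`, `count`, `fraction`, `ci_low`,
#'   `ci_high`.
#' @export
normalized_counts_ci <- function(tbl, sample, conf = 0.95) {
  validate_count_tbl(tbl)
  sub <- tbl[tbl$sample == sample, , drop = FALSE]
  if (nrow(sub) == 0L) abort(sprintf("Sample '%s' not found.", sample))
  total <- sum(sub$count)
  if (total == 0) abort(sprintf("Sample '%s' has zero total counts.", sample))
  ci <- wilson_interval(sub$count, total, conf)
  tibble(gene = sub$gene, class = sub$class, count = sub$count,
         fraction = sub$count / total, ci_low = ci[, "low"],
         ci_high = ci[, "high"])
}

#' Full depletion report for a control/treated sample pair
#'
#' Bundles the depletion statistics for one control and one treated sample:
#' per-class prevalences, reduction fold changes (flagging infinite folds
#' from complete depletion), spike-in correlation, and detection sets
#' between the two conditions.
#'
#' @param tbl A count tibble.
#' @param control_sample,treated_sample Sample ids.
#' @param min_count Detection threshold for [detection_sets()].
#' @return A `depletion_report` with [tidy()] and [glance()] methods.
#' @export
depletion_report <- function(tbl, control_sample, treated_sample,
                             min_count = 1) {
  validate_count_tbl(tbl)
  classes <- sort(unique(tbl$class))
  per_class <- bind_rows(map(classes, function(cl) {
    pc <- class_prevalence(tbl, control_sample, cl)
    pt <- class_prevalence(tbl, treated_sample, cl)
    fold <- if (pc > 0) reduction_fold(pc, pt) else NA_real_
    tibble(class = cl, prevalence_control = pc, prevalence_treated = pt,
           reduction_fold = fold, undefined = is.infinite(fold))
  }))
  globin <- intersect(c("globin_alpha", "globin_beta"), classes)
  g_ctl <- class_prevalence(tbl, control_sample, globin)
  g_trt <- class_prevalence(tbl, treated_sample, globin)
  cond_ctl <- unique(tbl$condition[tbl$sample == control_sample])[1L]
  cond_trt <- unique(tbl$condition[tbl$sample == treated_sample])[1L]
  r <- tryCatch(spikein_correlation(tbl, control_sample, treated_sample),
                error = function(e) NA_real_)
  sets <- detection_sets(tbl, cond_ctl, cond_trt, min_count = min_count)
  structure(
    list(
      per_class = per_class,
      globin_prevalence_control = g_ctl,
      globin_prevalence_treated = g_trt,
      globin_reduction_fold = reduction_fold(g_ctl, g_trt),
      spikein_r = r,
      detection = sets,
      control_sample = control_sample,
      treated_sample = treated_sample
    ),
    class = "depletion_report"
  )
}

#' @export
print.depletion_report <- function(x, ...) {
  cat(sprintf("<depletion_report> %s (control) vs %s (treated)\n",
              x$control_sample, x$treated_sample))
  cat(sprintf("  globin prevalence: %.1f%% -> %.1f%% (%.1fx reduction)\n",
              100 * x$globin_prevalence_control,
              100 * x$globin_prevalence_treated,
              x$globin_reduction_fold))
  cat(sprintf("  spike-in r: %s\n",
              ifelse(is.na(x$spikein_r), "NA", sprintf("%.3f", x$spikein_r))))
  cat(sprintf("  genes detected: %d shared, %d control-only, %d treated-only\n",
              length(x$detection$shared), length(x$detection$only_a),
              length(x$detection$only_b)))
  invisible(x)
}

#' @export
tidy.depletion_report <- function(x, ...) x$per_class

#' @export
glance.depletion_report <- function(x, ...) {
  tibble(
    globin_prevalence_control = x$globin_prevalence_control,
    globin_prevalence_treated = x$globin_prevalence_treated,
    globin_reduction_fold = x$globin_reduction_fold,
    spikein_r = x$spikein_r,
    n_shared = length(x$detection$shared),
    n_control_only = length(x$detection$only_a),
    n_treated_only = length(x$detection$only_b)
  )
}

#' Plot per-class prevalence for a depletion report
#'
#' @param object A `depletion_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.depletion_report <- function(object, ...) {
  d <- tidyr::pivot_longer(object$per_class,
                           c("prevalence_control", "prevalence_treated"),
                           names_to = "arm", values_to = "prevalence")
  d$arm <- sub("prevalence_", "", d$arm)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$prevalence,
                                  fill = .data$arm)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "fraction of sample counts", fill = NULL,
                  title = "Class prevalence, control vs treated") +
    ggplot2::theme_minimal()
}

# ---- qPCR ----------------------------------------------------------------

validate_qpcr_tbl <- function(q) {
  need <- c("sample", "target", "condition", "dilution_factor", "ct")
  if (!is.data.frame(q) || !all(need %in% names(q))) {
    abort(sprintf("qPCR tibble needs columns %s.", paste(need, collapse = ", ")))
  }
  if (any(q$ct <= 0)) abort("Ct values must be > 0.")
  if (any(q$dilution_factor < 1)) abort("`dilution_factor` must be >= 1.")
  invisible(q)
}

#' Relative qPCR fold change with quantification-range capping
#'
#' Computes the treated-vs-control fold change for one target from replicate
#' Ct values as `efficiency ^ (mean Ct_treated - mean Ct_control)`, using
#' the undiluted (`dilution_factor == 1`) replicates. In a dilution-limited
#' relative design the quantification range is bounded by the dilution
#' factor: with 10x template dilutions, folds up to 10 are measured
#' accurately and larger folds are reported but flagged out of range.
#'
#' @param q A qPCR tibble (`sample`, `target`, `condition`,
#'   `dilution_factor`, `ct`).
#' @param target Target gene.
#' @param efficiency Amplification efficiency in (1, 2]; 2 is perfect
#'   doubling. Estimate it from the dilution series with
#'   [qpcr_efficiency()].
#' @param condition_control,condition_treated Condition labels.
#'
#' @return A one-row tibble: `target`, `delta_ct`, `fold`, `dilution_factor`
#'   (the largest in the table for this target), `in_range`.
#' @export
qpcr_fold_change <- function(q, target, efficiency = 2,
                             condition_control = "control",
                             condition_treated = "treated") {
  validate_qpcr_tbl(q)
  if (efficiency <= 1 || efficiency > 2) abort("`efficiency` must be in (1, 2].")
  sub <- q[q$target == target, , drop = FALSE]
  if (nrow(sub) == 0L) abort(sprintf("Target '%s' not found.", target))
  base <- sub[sub$dilution_factor == 1, , drop = FALSE]
  ct_ctl <- base$ct[base$condition == condition_control]
  ct_trt <- base$ct[base$condition == condition_treated]
  if (!length(ct_ctl)) abort(sprintf("No '%s' replicates for target '%s'.",
                                     condition_control, target))
  if (!length(ct_trt)) abort(sprintf("No '%s' replicates for target '%s'.",
                                     condition_treated, target))
  dct <- mean(ct_trt) - mean(ct_ctl)
  fold <- efficiency^dct
  dil <- max(sub$dilution_factor)
  tibble(target = target, delta_ct = dct, fold = fold,
         dilution_factor = dil, in_range = fold <= dil)
}

#' Amplification efficiency from a dilution series
#'
#' Least-squares fit of Ct against log10 template amount (i.e.
#' `-log10(dilution_factor)`); the efficiency is `10^(-1/slope)`. A perfect
#' doubling series has slope -3.3219 and efficiency 2.
#'
#' @param dilution_series A data frame with columns `dilution_factor`
#'   (>= 1; 10 means 10x diluted) and `ct`.
#' @return The estimated efficiency.
#' @export
qpcr_efficiency <- function(dilution_series) {
  d <- dilution_series
  if (!all(c("dilution_factor", "ct") %in% names(d))) {
    abort("`dilution_series` needs columns `dilution_factor` and `ct`.")
  }
  if (length(unique(d$dilution_factor)) < 2L) {
    abort("Need at least 2 distinct dilutions to estimate efficiency.")
  }
  slope <- coef(lm(ct ~ I(-log10(dilution_factor)), data = d))[[2L]]
  10^(-1 / slope)
}
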