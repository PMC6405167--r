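#' Design of the subsampling detection-limit experiment
#'
#' Mirrors the validation layout for small case cohorts: repeated random
#' subsamples of the cases at several sizes, each scanned against the full
#' control set.
#'
#' @param sample_sizes Case counts to subsample (default `c(20, 30, 40, 50)`).
#' @param replicates Random subsamples per size (default 10).
#' @param n_controls Controls used per scan (default 1000).
#' @param seed Master seed; replicate r at size index s runs on an
#'   independent substream derived as `(seed * 131 + s * 17 + r) mod 2^31-1`,
#'   so curves do not depend on loop order.
#' @param alpha Detection threshold on the BH-adjusted p-value (default 0.05).
#' @return List of class `subsample_design`.
#' @export
subsample_design <- function(sample_sizes = c(20L, 30L, 40L, 50L),
                             replicates = 10L, n_controls = 1000L,
                             seed = 1L, alpha = 0.05) {
  stopifnot(length(sample_sizes) >= 1L, replicates >= 1L, n_controls >= 1L,
            alpha > 0, alpha < 1)
  structure(list(sample_sizes = as.integer(sample_sizes),
                 replicates = as.integer(replicates),
                 n_controls = as.integer(n_controls),
                 seed = as.integer(seed), alpha = alpha),
            class = "subsample_design")
}

substream_seed <- function(master, size_index, replicate) {
  as.integer((as.numeric(master) * 131 + size_index * 17 + replicate) %%
               2147483647)
}

split_cohort <- function(cohort) {
  g <- cohort$genotypes
  list(cases = g[g$group == "case", , drop = FALSE],
       controls = g[g$group == "control", , drop = FALSE])
}

#' Subsample cases and scan for the strongest motif association
#'
#' For every (sample size, replicate) cell, draws that many cases without
#' replacement (subjects keyed and ordered by id, so the draw depends only on
#' the substream seed), pairs them with the controls, runs the full motif
#' scan, and records the family-minimum raw and adjusted p-values.  When the
#' embedded true motif is known it is also located in the result family.
#'
#' @param cases,controls `hla_cohort` objects holding the case pool and the
#'   control pool (each may also be a mixed cohort; the relevant group is
#'   extracted).
#' @param catalog An [hla_catalog()].
#' @param design A [subsample_design()].
#' @param config A [scan_config()] passed to [scan_all()].
#' @param true_motif Optional [motif()]: the embedded effect to track.
#' @return List of class `detection_curve`: `cells` (data frame with one row
#'   per size x replicate: `size`, `replicate`, `min_p_raw`, `min_p_adj`,
#'   `neglog10_min_p_raw`, `neglog10_min_p_adj`, `detected`, and when
#'   `true_motif` is given `true_p_raw`, `true_p_adj`, `true_rank`,
#'   `detected_true`), plus the `design`.
#' @export
subsample_and_scan <- function(cases, controls, catalog, design,
                               config = scan_config(), true_motif = NULL) {
  stopifnot(inherits(design, "subsample_design"))
  case_g <- if (inherits(cases, "hla_cohort")) {
    split_cohort(cases)$cases
  } else cases
  ctrl_g <- if (inherits(controls, "hla_cohort")) {
    split_cohort(controls)$controls
  } else controls
  if (nrow(ctrl_g) == 0L) stop("empty control pool", call. = FALSE)
  if (nrow(case_g) < max(design$sample_sizes)) {
    stop("insufficient cases: pool of ", nrow(case_g), " < max sample size ",
         max(design$sample_sizes), call. = FALSE)
  }
  case_g <- case_g[order(case_g$subject_id), , drop = FALSE]
  ctrl_g <- ctrl_g[order(ctrl_g$subject_id), , drop = FALSE]

  cells <- list()
  for (si in seq_along(design$sample_sizes)) {
    size <- design$sample_sizes[[si]]
    for (r in seq_len(design$replicates)) {
      sub_seed <- substream_seed(design$seed, si, r)
      sub <- withr::with_seed(sub_seed, {
        ci <- sample.int(nrow(case_g), size)
        ki <- if (nrow(ctrl_g) > design$n_controls) {
          sample.int(nrow(ctrl_g), design$n_controls)
        } else seq_len(nrow(ctrl_g))
        rbind(case_g[ci, , drop = FALSE], ctrl_g[ki, , drop = FALSE])
      })
      scan <- scan_all(hla_cohort(sub), catalog, config = config)
      res <- scan$results
      if (nrow(res) == 0L) {
        stop("scan produced no motifs; catalog is monomorphic", call. = FALSE)
      }
      cell <- data.frame(
        size = size, replicate = r,
        min_p_raw = min(res$p_raw), min_p_adj = min(res$p_adjusted))
      cell$neglog10_min_p_raw <- -log10(cell$min_p_raw)
      cell$neglog10_min_p_adj <- -log10(cell$min_p_adj)
      cell$detected <- cell$min_p_adj < design$alpha
      if (!is.null(true_motif)) {
        hit <- res$locus == true_motif$locus &
          res$positions == paste(true_motif$positions, collapse = ";") &
          res$residues == paste(true_motif$residues, collapse = ";")
        if (!any(hit)) {
          cell$true_p_raw <- NA_real_; cell$true_p_adj <- NA_real_
          cell$true_rank <- NA_integer_; cell$detected_true <- FALSE
        } else {
          cell$true_p_raw <- res$p_raw[hit][[1L]]
          cell$true_p_adj <- res$p_adjusted[hit][[1L]]
          cell$true_rank <- sum(res$p_raw < cell$true_p_raw) + 1L
          cell$detected_true <- cell$true_p_adj < design$alpha
        }
      }
      cells[[length(cells) + 1L]] <- cell
    }
  }
  structure(list(cells = do.call(rbind, cells), design = design),
            class = "detection_curve")
}

#' Summarise a detection curve
#'
#' @param curve A `detection_curve` from [subsample_and_scan()].
#' @return Data frame with one row per sample size: `detection_frequency`
#'   (family-minimum adjusted p below alpha), `median_neglog10_p_raw`,
#'   `min_neglog10_p_raw`, `median_neglog10_p_adj`, and when the true motif
#'   was tracked `detection_frequency_true` and `median_true_rank`.
#' @export
detection_report <- function(curve) {
  stopifnot(inherits(curve, "detection_curve"))
  cells <- curve$cells
  out <- do.call(rbind, lapply(split(cells, cells$size), function(d) {
    row <- data.frame(
      size = d$size[[1L]], replicates = nrow(d),
      detection_frequency = mean(d$detected),
      median_neglog10_p_raw = stats::median(d$neglog10_min_p_raw),
      min_neglog10_p_raw = min(d$neglog10_min_p_raw),
      median_neglog10_p_adj = stats::median(d$neglog10_min_p_adj))
    if ("detected_true" %in% names(d)) {
      row$detection_frequency_true <- mean(d$detected_true)
      row$median_true_rank <- stats::median(d$true_rank)
    }
    row
  }))
  out <- out[order(out$size), ]
  rownames(out) <- NULL
  out
}

#' @export
print.detection_curve <- function(x, ...) {
  print(detection_report(x))
  invisible(x)
}
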