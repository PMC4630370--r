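# Peptide-to-protein quantification: aggregation of reporter ratios,
# normalisation, median/SD significance thresholds, differential calls
# including ON/OFF, and trend grouping over the treatment time course.

#' Time points of the treatment course
#'
#' The three treatment durations quantified against the untreated control
#' (reporter channels 115, 116, 117 vs 114).
#' @export
TIMEPOINTS <- c("40min", "2h", "5h")

ratio_cols <- function() paste0("ratio_", TIMEPOINTS)
fc_cols <- function() paste0("fc_", TIMEPOINTS)
status_cols <- function() paste0("status_", TIMEPOINTS)
sig_cols <- function() paste0("sig_", TIMEPOINTS)

#' Average peptide ratios to a protein ratio
#'
#' Ratios are averaged in log space (geometric mean), the symmetric choice
#' for fold-change data: `protein_ratio(c(r, 1/r))` is 1 for any `r`.
#'
#' @param peptide_ratios Positive numeric vector of peptide-level ratios.
#' @return The geometric mean.
#' @export
protein_ratio <- function(peptide_ratios) {
  if (length(peptide_ratios) == 0L) stop("no peptide ratios to average", call. = FALSE)
  if (any(!is.finite(peptide_ratios)) || any(peptide_ratios <= 0)) {
    stop("peptide ratios must be positive and finite", call. = FALSE)
  }
  exp(mean(log(peptide_ratios)))
}

#' Signed fold change
#'
#' Expresses a treated/control ratio `r` on the symmetric fold-change scale:
#' `r` when `r >= 1`, `-1/r` when `r < 1`, so downregulation is negative and
#' `|FC| >= 1` always.
#'
#' @param ratio Positive numeric vector (NA passed through).
#' @return Signed fold changes.
#' @examples
#' signed_fold_change(c(4, 1, 0.25))  # 4, 1, -4
#' @export
signed_fold_change <- function(ratio) {
  if (any(ratio <= 0, na.rm = TRUE)) stop("ratios must be positive", call. = FALSE)
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' Inverse of [signed_fold_change()]
#' @param fc Signed fold changes (|fc| >= 1).
#' @return Ratios on (0, Inf).
#' @export
ratio_from_signed <- function(fc) {
  if (any(abs(fc) < 1, na.rm = TRUE)) {
    stop("signed fold changes have absolute value >= 1", call. = FALSE)
  }
  ifelse(fc >= 0, fc, -1 / fc)
}

#' Normalise protein ratios per time point
#'
#' Median centring: every ratio in a time-point column is divided by that
#' column's median ratio (equivalently, the median log ratio is subtracted
#' in log space), so the post-normalisation column median is exactly 1 and
#' unchanged proteins sit at ratio 1.
#'
#' @param x A protein quant table (data frame with `ratio_40min`,
#'   `ratio_2h`, `ratio_5h` columns; NA entries, e.g. ON/OFF proteins, are
#'   ignored in the median and passed through) or a numeric matrix of
#'   ratios with time points in columns.
#' @return Object of the same shape with normalised ratios.
#' @export
normalize_ratios <- function(x) {
  norm_col <- function(v) {
    if (any(v <= 0, na.rm = TRUE)) stop("ratios must be positive", call. = FALSE)
    v / stats::median(v, na.rm = TRUE)
  }
  if (is.data.frame(x)) {
    for (cl in intersect(ratio_cols(), names(x))) x[[cl]] <- norm_col(x[[cl]])
    x
  } else {
    apply(x, 2, norm_col)
  }
}

#' Differential-expression thresholds from the population median and SD
#'
#' For each time point the threshold on the log2 scale is
#' `|median| + z * SD` of the (normalised) log2 ratio population, with
#' `z = qnorm(1 - p_level/2)` (two-sided; 1.6449 at `p_level = 0.1`).
#' The threshold is reported on the symmetric signed-fold-change scale as
#' `tau = 2^(|median| + z*SD)`, the bound exceeded with probability
#' `p_level` under a Gaussian log-ratio population.
#'
#' @param log2_ratios Matrix or data frame of normalised log2 ratios, one
#'   column per time point (NA ignored); each column needs at least 3
#'   values.
#' @param p_level Two-sided significance level (default 0.1).
#' @return A `de_thresholds` data frame with columns `time`, `tau_log2`,
#'   `tau`, and attributes `z` and `p_level`.
#' @export
compute_thresholds <- function(log2_ratios, p_level = 0.1) {
  log2_ratios <- as.matrix(log2_ratios)
  z <- stats::qnorm(1 - p_level / 2)
  res <- apply(log2_ratios, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 3) stop("need at least 3 log2 ratios per time point", call. = FALSE)
    abs(stats::median(v)) + z * stats::sd(v)
  })
  tm <- colnames(log2_ratios)
  if (is.null(tm)) tm <- TIMEPOINTS[seq_along(res)]
  out <- data.frame(time = tm, tau_log2 = unname(res), tau = unname(2^res),
                    stringsAsFactors = FALSE)
  attr(out, "z") <- z
  attr(out, "p_level") <- p_level
  class(out) <- c("de_thresholds", "data.frame")
  out
}

#' Call differentially expressed proteins
#'
#' A protein is significant at a time point iff the absolute signed fold
#' change meets the per-time-point threshold (inclusive, `>=`) and indicates
#' an actual change (`|FC| > 1`), or its status there is ON (detected only
#' under treatment) or OFF (detected only in the control), which is
#' significant by definition.
#'
#' @param quant Quant table with `fc_40min`/`fc_2h`/`fc_5h` signed
#'   fold-change columns and optional `status_*` columns ("normal", "ON",
#'   "OFF").
#' @param thresholds A `de_thresholds` object from [compute_thresholds()],
#'   or a numeric vector of per-time-point fold-change thresholds (e.g.
#'   `c(2.6, 2.6, 2.4)` for reference-table replay).
#' @return `quant` with logical `sig_40min`/`sig_2h`/`sig_5h` columns added.
#' @export
call_differential <- function(quant, thresholds) {
  tau <- if (inherits(thresholds, "de_thresholds")) thresholds$tau else as.numeric(thresholds)
  stopifnot(length(tau) == length(TIMEPOINTS), all(tau >= 1))
  for (i in seq_along(TIMEPOINTS)) {
    tp <- TIMEPOINTS[i]
    fc <- quant[[paste0("fc_", tp)]]
    st <- quant[[paste0("status_", tp)]]
    if (is.null(st)) st <- rep("normal", length(fc))
    onoff <- st %in% c("ON", "OFF")
    # |FC| > 1 guard: at a degenerate threshold of 1 (zero-variance
    # population) an unchanged protein must not be called; the 1e-8 slack
    # keeps round-off from the ratio fit from registering as a change
    sig <- onoff | (!is.na(fc) & abs(fc) >= tau[i] & abs(fc) > 1 + 1e-8)
    quant[[paste0("sig_", tp)]] <- sig
  }
  quant
}

#' Group proteins by their temporal expression trend
#'
#' Each protein's trajectory is discretised per time point to one of
#' `down`, `none`, `up`, `ON`, `OFF` (`up`/`down` only where the call is
#' significant) and proteins sharing a trajectory are grouped.
#'
#' @param calls Quant table with `fc_*`, `status_*` and `sig_*` columns
#'   (see [call_differential()]) and an `accession` column.
#' @return Data frame with one row per trajectory pattern: `pattern`
#'   (e.g. "down/none/none"), `n`, `proteins` (";"-separated), sorted by
#'   group size descending.
#' @export
cluster_trends <- function(calls) {
  pat <- vapply(seq_len(nrow(calls)), function(r) {
    states <- vapply(TIMEPOINTS, function(tp) {
      st <- calls[[paste0("status_", tp)]]
      st <- if (is.null(st)) "normal" else st[r]
      if (st %in% c("ON", "OFF")) return(st)
      if (!isTRUE(calls[[paste0("sig_", tp)]][r])) return("none")
      if (calls[[paste0("fc_", tp)]][r] > 0) "up" else "down"
    }, character(1))
    paste(states, collapse = "/")
  }, character(1))
  groups <- split(calls$accession, pat)
  out <- data.frame(pattern = names(groups),
                    n = lengths(groups),
                    proteins = vapply(groups, paste, character(1), collapse = ";"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$n, out$pattern), , drop = FALSE]
}

#' Peptide-level ratio table from reporter fits
#'
#' Extracts treated/control ratios (channels 115/116/117 over 114) and
#' channel detection flags from a list of reporter fits.
#'
#' @param fits List of `reporter_fit` objects (see
#'   [fit_reporter_ratios()]).
#' @param peptides Character vector of peptide identifiers, parallel to
#'   `fits`.
#' @return Data frame with columns `peptide`, `gof`, `r_40min`, `r_2h`,
#'   `r_5h` (`Inf` where the control channel is below detection but the
#'   treated channel is detected, `0` for the reverse, `NA` when neither is
#'   detected) and detection flags.
#' @export
peptide_ratio_table <- function(fits, peptides) {
  stopifnot(length(fits) == length(peptides))
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    co <- f$coefficients
    det <- f$detected
    r <- vapply(2:4, function(ch) {
      if (det[1] && det[ch]) co[ch] / co[1]
      else if (!det[1] && det[ch]) Inf
      else if (det[1] && !det[ch]) 0
      else NA_real_
    }, numeric(1))
    d <- data.frame(peptide = peptides[i], gof = f$gof,
                    t(r), det_ctrl = det[1], t(det[2:4]),
                    stringsAsFactors = FALSE)
    names(d)[3:5] <- paste0("r_", TIMEPOINTS)
    names(d)[7:9] <- paste0("det_", TIMEPOINTS)
    d
  })
  do.call(rbind, rows)
}

#' Aggregate peptide fits to a protein quant table
#'
#' Applies the GOF filter, maps peptides to proteins, and per protein and
#' time point either averages the peptide ratios (geometric mean) or calls
#' status ON (control channel below detection in every peptide, treated
#' detected) / OFF (treated below detection, control detected).
#'
#' @param peptide_table Output of [peptide_ratio_table()].
#' @param peptide_map Named character vector: peptide -> protein accession.
#' @param min_gof GOF cutoff (default 0.8); fits below it are discarded.
#' @return Protein quant table: `accession`, `n_peptides`, `ratio_*`
#'   (NA for ON/OFF), `status_*`.
#' @export
protein_quant <- function(peptide_table, peptide_map, min_gof = 0.8) {
  keep <- peptide_table$gof >= min_gof
  if (!any(keep)) {
    stop("no peptide quantification passed the GOF filter (min_gof = ",
         min_gof, ")", call. = FALSE)
  }
  pt <- peptide_table[keep, , drop = FALSE]
  unmapped <- setdiff(pt$peptide, names(peptide_map))
  if (length(unmapped)) {
    stop("peptides not in the peptide->protein map: ",
         paste(utils::head(unmapped, 5), collapse = ", "), call. = FALSE)
  }
  prot <- unname(peptide_map[pt$peptide])
  rows <- lapply(split(seq_len(nrow(pt)), prot), function(idx) {
    sub <- pt[idx, , drop = FALSE]
    ratio <- numeric(length(TIMEPOINTS)); status <- character(length(TIMEPOINTS))
    for (i in seq_along(TIMEPOINTS)) {
      v <- sub[[paste0("r_", TIMEPOINTS[i])]]
      v <- v[!is.na(v)]
      if (length(v) && all(is.infinite(v))) {
        ratio[i] <- NA_real_; status[i] <- "ON"
      } else if (length(v) && all(v == 0)) {
        ratio[i] <- NA_real_; status[i] <- "OFF"
      } else {
        fin <- v[is.finite(v) & v > 0]
        if (length(fin)) {
          ratio[i] <- protein_ratio(fin); status[i] <- "normal"
        } else {
          ratio[i] <- NA_real_; status[i] <- "normal"
        }
      }
    }
    d <- data.frame(accession = unname(peptide_map[sub$peptide[1]]),
                    n_peptides = nrow(sub), t(ratio), t(status),
                    stringsAsFactors = FALSE)
    names(d)[3:5] <- ratio_cols()
    names(d)[6:8] <- status_cols()
    d
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$accession), , drop = FALSE]
}

#' Signed fold changes for a quant table
#'
#' Adds `fc_*` columns (signed fold change of the `ratio_*` columns) to a
#' protein quant table.
#'
#' @param quant Protein quant table with `ratio_*` columns.
#' @return `quant` with `fc_40min`, `fc_2h`, `fc_5h` added.
#' @export
add_signed_fc <- function(quant) {
  for (tp in TIMEPOINTS) {
    quant[[paste0("fc_", tp)]] <- signed_fold_change(quant[[paste0("ratio_", tp)]])
  }
  quant
}
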