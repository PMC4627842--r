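# Post-hoc analyses: disordered-residue composition profiles, region-level
# structural characterization, and the monogram/bigram distribution check.

#' Residue-composition profile of disordered residues
#'
#' For each amino-acid type j, computes the actual ratio r_a(j) = (number
#' of truly disordered residues of type j) / (all truly disordered
#' residues) and the analogous predicted ratio r_p(j) from the binary
#' calls, plus the RMSE over the 20 types and the Pearson correlation of
#' the two vectors.
#'
#' @param truth Per-residue labels over \code{c("O","D","U")}.
#' @param calls Per-residue predicted calls over \code{c("O","D")}.
#' @param residues Per-residue one-letter codes, aligned with the labels.
#' @return List of class \code{composition_profile}: \code{r_a}, \code{r_p}
#'   (named 20-vectors in alphabetical order), \code{rmse}, \code{pcc}.
#' @export
composition_profile <- function(truth, calls, residues) {
  stopifnot(length(truth) == length(calls),
            length(truth) == length(residues))
  known <- truth != "U"
  da <- residues[known & truth == "D"]
  dp <- residues[known & calls == "D"]
  if (!length(da) || !length(dp))
    stop("no disordered residues in actual or predicted set")
  frac <- function(res) {
    tab <- table(factor(res, levels = AA_ALPHABET))
    as.numeric(tab) / length(res)
  }
  r_a <- stats::setNames(frac(da), AA_ALPHABET)
  r_p <- stats::setNames(frac(dp), AA_ALPHABET)
  structure(list(r_a = r_a, r_p = r_p,
                 rmse = sqrt(mean((r_a - r_p)^2)),
                 pcc = stats::cor(r_a, r_p)),
            class = "composition_profile")
}

#' Region-level structural characterization
#'
#' After trimming \code{terminal_trim} residues from each chain end
#' (terminal residues are surface-exposed and conformationally atypical),
#' splits the remaining labels into maximal same-label runs and reports,
#' per run: the mean predicted coil probability P_coil and the fraction of
#' residues with relative solvent accessibility strictly greater than 0.25
#' (F_exposed).
#'
#' @param labels Per-residue labels of one chain.
#' @param structural The chain's \code{structural_profile}.
#' @param terminal_trim Residues discarded from each end (default 5).
#' @param id Chain identifier for messages.
#' @return Data frame with one row per region: \code{label}, \code{start},
#'   \code{end} (1-based inclusive, original coordinates), \code{p_coil},
#'   \code{f_exposed}; or \code{NULL} (with a warning) for chains shorter
#'   than \code{2 * terminal_trim + 1}.
#' @export
region_stats <- function(labels, structural, terminal_trim = 5L, id = "?") {
  stopifnot(inherits(structural, "structural_profile"),
            length(labels) == nrow(structural$tab))
  L <- length(labels)
  if (L < 2L * terminal_trim + 1L) {
    warning("chain '", id, "' shorter than ", 2L * terminal_trim + 1L,
            " residues; skipped", call. = FALSE)
    return(NULL)
  }
  span <- (terminal_trim + 1L):(L - terminal_trim)
  lab <- labels[span]
  runs <- rle(lab)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  do.call(rbind, lapply(seq_along(runs$values), function(i) {
    idx <- span[starts[i]:ends[i]]
    data.frame(label = runs$values[i],
               start = idx[1], end = idx[length(idx)],
               p_coil = mean(structural$tab$p_coil[idx]),
               f_exposed = mean(structural$tab$asa[idx] > 0.25),
               stringsAsFactors = FALSE)
  }))
}

#' Monogram/bigram distribution summary
#'
#' Pools the un-normalized monogram and bigram values (i.e. the raw sums,
#' before division by e^6) across profiles and summarizes their natural-log
#' distributions.  On realistic profile data both log-medians sit near 6,
#' which is the rationale for the e^6 normalizer.
#'
#' @param profiles List of \code{pssm_profile} objects.
#' @return List of class \code{mgbg_distribution}: \code{mg_log_median},
#'   \code{bg_log_median}, and \code{mg_hist}/\code{bg_hist} (histogram
#'   summaries of the log values).
#' @export
mgbg_distribution <- function(profiles) {
  if (!length(profiles)) stop("at least one profile is required")
  vals <- lapply(profiles, function(p) {
    tabs <- monogram_bigram(normalize_pssm(p$scores))
    list(mg = as.numeric(tabs$mg) * MGBG_NORMALIZER,
         bg = as.numeric(tabs$bg) * MGBG_NORMALIZER)
  })
  mg <- log(unlist(lapply(vals, `[[`, "mg")))
  bg <- log(unlist(lapply(vals, `[[`, "bg")))
  structure(list(mg_log_median = stats::median(mg),
                 bg_log_median = stats::median(bg),
                 mg_hist = graphics::hist(mg, plot = FALSE),
                 bg_hist = graphics::hist(bg, plot = FALSE)),
            class = "mgbg_distribution")
}

#' @export
print.mgbg_distribution <- function(x, ...) {
  cat(sprintf("log-scale medians: MG %.3f, BG %.3f (e^6 normalizer targets 6)\n",
              x$mg_log_median, x$bg_log_median))
  invisible(x)
}
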