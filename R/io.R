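# Readers and writers for every external file the pipeline touches:
# FASTA sequences, PSI-BLAST ASCII PSSMs, structural profiles, per-residue
# disorder annotations, prediction files and model archives.

#' Construct an annotated protein
#'
#' Bundles a chain identifier, its amino-acid sequence and per-residue
#' three-state labels (\code{"O"} order, \code{"D"} disorder, \code{"U"}
#' unknown).  Unknown residues are retained here; they are excluded from
#' training and evaluation downstream but still contribute as window
#' neighbours during featurization.
#'
#' @param id Chain identifier.
#' @param sequence Uppercase amino-acid sequence (one-letter codes).
#' @param labels Character vector over \code{c("O","D","U")}, one per
#'   residue.  Defaults to all-unknown (for prediction-only inputs).
#' @return An object of class \code{annotated_protein}.
#' @export
annotated_protein <- function(id, sequence,
                              labels = rep("U", nchar(sequence))) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) < 1L)
    stop("protein '", id, "': sequence is empty")
  labels <- as.character(labels)
  if (length(labels) != nchar(sequence))
    stop("protein '", id, "': ", length(labels), " labels for ",
         nchar(sequence), " residues")
  bad <- setdiff(unique(labels), LABEL_CODES)
  if (length(bad))
    stop("protein '", id, "': unknown label symbol(s) ",
         paste(sQuote(bad), collapse = ", "))
  structure(list(id = id, sequence = sequence, labels = labels),
            class = "annotated_protein")
}

#' @export
print.annotated_protein <- function(x, ...) {
  n <- nchar(x$sequence)
  cat(sprintf("<annotated_protein> %s: %d residues (%d D, %d O, %d U)\n",
              x$id, n, sum(x$labels == "D"), sum(x$labels == "O"),
              sum(x$labels == "U")))
  invisible(x)
}

#' Read a FASTA file
#'
#' Parses a FASTA file into a list of \code{(id, sequence)} pairs in file
#' order, sequences uppercased.  Sequences are returned verbatim (including
#' any non-standard letters); apply [validate_protein()] downstream to
#' enforce the residue alphabet.
#'
#' @param path Path to a FASTA file.
#' @return Named list of uppercase sequence strings; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readAAStringSet(path)
    seqs <- toupper(as.character(set))
    names(seqs) <- vapply(strsplit(names(set), "[ \t]"), `[`, "", 1L)
  } else {
    lines <- readLines(path)
    hdr <- grepl("^>", lines)
    if (!any(hdr) || !hdr[1L])
      stop("not FASTA-formatted (no leading '>'): ", path)
    grp <- cumsum(hdr)
    ids <- sub("^>", "", lines[hdr])
    ids <- vapply(strsplit(ids, "[ \t]"), `[`, "", 1L)
    seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                   function(x) toupper(paste(gsub("\\s", "", x), collapse = "")),
                   "")
    names(seqs) <- ids
  }
  if (anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("malformed FASTA header in ", path)
  empty <- nchar(seqs) == 0L
  if (any(empty))
    stop("empty sequence for record(s): ",
         paste(names(seqs)[empty], collapse = ", "))
  as.list(seqs)
}

#' Validate a protein sequence against the standard residue alphabet
#'
#' Sequences containing letters outside the 20 standard one-letter codes
#' (for example the unknown-residue tag \code{X}) are either skipped
#' (returning \code{NULL} with a warning, the default, matching the usual
#' dataset-purification step) or rejected with an error naming the first
#' offending position.
#'
#' @param seq Uppercase sequence string.
#' @param policy \code{"skip"} (default) or \code{"reject"}.
#' @param id Optional identifier used in messages.
#' @return The sequence, or \code{NULL} if skipped.
#' @export
validate_protein <- function(seq, policy = c("skip", "reject"), id = "?") {
  policy <- match.arg(policy)
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!(chars %in% AA_ALPHABET))
  if (!length(bad)) return(seq)
  if (policy == "reject")
    stop("protein '", id, "': non-standard residue '", chars[bad[1]],
         "' at position ", bad[1])
  warning("protein '", id, "' skipped: non-standard residue '",
          chars[bad[1]], "' at position ", bad[1], call. = FALSE)
  NULL
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the ASCII position-specific scoring matrix written by PSI-BLAST
#' (the \code{-Q} output).  Header lines are skipped; for each residue row
#' the first 20 numeric columns after the position index and residue letter
#' are taken as log-odds (the trailing percentage and statistics columns are
#' ignored).
#'
#' @param path Path to the ASCII PSSM file.
#' @param sequence Optional sequence; when given, row residue letters are
#'   cross-checked against it.
#' @param id Identifier stored on the result (default: file base name).
#' @return An object of class \code{pssm_profile}: list with \code{id} and
#'   an L x 20 integer-valued \code{scores} matrix in PSI-BLAST column order.
#' @export
read_pssm <- function(path, sequence = NULL,
                      id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  rows <- list(); letters_seen <- character()
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(toks) < 2L) next
    # residue rows start "<index> <letter> <20+ numbers>"
    if (!grepl("^[0-9]+$", toks[1]) || !grepl("^[A-Za-z]$", toks[2])) next
    nums <- suppressWarnings(as.numeric(toks[-(1:2)]))
    if (anyNA(nums[seq_len(min(20, length(nums)))]) || length(nums) < 20L)
      stop("PSSM ", path, " line ", i, ": expected >= 20 score columns, got ",
           sum(!is.na(nums)))
    rows[[length(rows) + 1L]] <- nums[1:20]
    letters_seen <- c(letters_seen, toupper(toks[2]))
  }
  if (!length(rows)) stop("no PSSM rows found in ", path)
  scores <- do.call(rbind, rows)
  colnames(scores) <- PSSM_COLUMNS
  if (!is.null(sequence)) {
    chars <- strsplit(toupper(sequence), "")[[1]]
    if (length(chars) != nrow(scores))
      stop("PSSM ", id, ": ", nrow(scores), " rows for sequence of length ",
           length(chars))
    mis <- which(chars != letters_seen)
    if (length(mis))
      stop("PSSM ", id, ": residue letter mismatch at position ", mis[1],
           " ('", letters_seen[mis[1]], "' vs sequence '", chars[mis[1]], "')")
  }
  structure(list(id = id, scores = scores, residues = letters_seen),
            class = "pssm_profile")
}

#' Read a per-residue structural profile
#'
#' Tabular text, one row per residue with columns: index, residue letter,
#' predicted helix/sheet/coil probabilities, predicted relative solvent
#' accessibility, and predicted phi/psi torsion-angle fluctuations.
#' Secondary-structure probabilities must sum to 1 within a tolerance of
#' 0.05 per row (upstream predictors are approximate).
#'
#' @param path Path to the profile file.
#' @param sequence Optional sequence for a length/letter cross-check.
#' @param id Identifier (default: file base name).
#' @return An object of class \code{structural_profile}: list with \code{id}
#'   and a data frame of \code{p_helix, p_sheet, p_coil, asa, dphi, dpsi}.
#' @export
read_structural_profile <- function(path, sequence = NULL,
                                    id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 8L)
    stop("structural profile ", path, ": expected 8 columns, got ", ncol(df))
  names(df)[1:8] <- c("pos", "res", "p_helix", "p_sheet", "p_coil",
                      "asa", "dphi", "dpsi")
  structural_profile(id, df[c("p_helix", "p_sheet", "p_coil",
                              "asa", "dphi", "dpsi")],
                     residues = toupper(df$res), sequence = sequence)
}

#' Construct a structural profile
#'
#' @param id Chain identifier.
#' @param tab Data frame with columns \code{p_helix, p_sheet, p_coil, asa,
#'   dphi, dpsi}, one row per residue.
#' @param residues Optional residue letters for cross-checking.
#' @param sequence Optional sequence for cross-checking.
#' @return An object of class \code{structural_profile}.
#' @export
structural_profile <- function(id, tab, residues = NULL, sequence = NULL) {
  need <- c("p_helix", "p_sheet", "p_coil", "asa", "dphi", "dpsi")
  stopifnot(all(need %in% names(tab)))
  tab <- as.data.frame(tab)[need]
  if (nrow(tab) < 1L) stop("structural profile '", id, "' is empty")
  ss_sum <- tab$p_helix + tab$p_sheet + tab$p_coil
  if (any(abs(ss_sum - 1) > 0.05))
    stop("structural profile '", id,
         "': secondary-structure probabilities do not sum to 1 (row ",
         which(abs(ss_sum - 1) > 0.05)[1], ")")
  if (any(tab$asa < 0 | tab$asa > 1))
    stop("structural profile '", id, "': asa outside [0,1]")
  if (any(tab$dphi < 0 | tab$dpsi < 0))
    stop("structural profile '", id, "': negative torsion fluctuation")
  if (!is.null(sequence)) {
    chars <- strsplit(toupper(sequence), "")[[1]]
    if (length(chars) != nrow(tab))
      stop("structural profile '", id, "': ", nrow(tab),
           " rows for sequence of length ", length(chars))
    if (!is.null(residues)) {
      mis <- which(chars != residues)
      if (length(mis))
        stop("structural profile '", id,
             "': residue letter mismatch at position ", mis[1])
    }
  }
  structure(list(id = id, tab = tab), class = "structural_profile")
}

#' Read per-residue disorder annotations
#'
#' Tabular text, one row per residue: 1-based index, residue letter, label
#' symbol in \code{O} (order), \code{D} (disorder), \code{U} (unknown).
#'
#' @param path Path to the annotation file.
#' @param sequence Optional sequence; length and letters cross-checked.
#' @return Character vector of labels over \code{c("O","D","U")}.
#' @export
read_annotation <- function(path, sequence = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop("annotation ", path, ": expected 3 columns, got ", ncol(df))
  labels <- toupper(as.character(df[[3]]))
  bad <- which(!(labels %in% LABEL_CODES))
  if (length(bad))
    stop("annotation ", path, ": unknown label symbol '", labels[bad[1]],
         "' at row ", bad[1])
  if (!is.null(sequence)) {
    chars <- strsplit(toupper(sequence), "")[[1]]
    if (length(chars) != length(labels))
      stop("annotation ", path, ": ", length(labels),
           " rows for sequence of length ", length(chars))
    mis <- which(chars != toupper(as.character(df[[2]])))
    if (length(mis))
      stop("annotation ", path, ": residue letter mismatch at position ",
           mis[1])
  }
  labels
}

#' Write per-residue disorder predictions
#'
#' Tab-separated text with one block per protein.  Each block starts with a
#' header line \code{>id} followed by one row per residue: 1-based index,
#' residue letter, disorder probability to 6 decimal places, and the binary
#' call (\code{+1} disorder, \code{-1} order).
#'
#' @param records List of prediction records as returned by
#'   [predict_disorder()]: each a list with \code{id}, \code{residues},
#'   \code{prob} and \code{call} (\code{"D"}/\code{"O"}).
#' @param path Output file path.
#' @export
write_predictions <- function(records, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (r in records) {
    stopifnot(all(r$prob >= 0 & r$prob <= 1))
    writeLines(paste0(">", r$id), con)
    writeLines(sprintf("%d\t%s\t%.6f\t%s",
                       seq_along(r$prob), r$residues,
                       r$prob, ifelse(r$call == "D", "+1", "-1")), con)
  }
  invisible(path)
}

#' Read a prediction file written by [write_predictions()]
#'
#' @param path Path to the prediction file.
#' @return List of prediction records (\code{id}, \code{residues},
#'   \code{prob}, \code{call}).
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1L]) stop("not a prediction file: ", path)
  grp <- cumsum(hdr)
  ids <- sub("^>", "", lines[hdr])
  lapply(seq_along(ids), function(j) {
    block <- lines[!hdr & grp == j]
    toks <- strsplit(block, "\t")
    prob <- vapply(toks, function(t) as.numeric(t[3]), 0)
    call <- vapply(toks, function(t) t[4], "")
    list(id = ids[j],
         residues = vapply(toks, function(t) t[2], ""),
         prob = prob,
         call = ifelse(call == "+1", "D", "O"))
  })
}

MODEL_FORMAT_VERSION <- "idpred-model-1"

#' Save / load a trained model bundle
#'
#' The archive holds the trained classifier, the feature scaler, all
#' hyperparameters (window size, cost, gamma, decision threshold,
#' oversampling factor), the sigmoid calibration coefficients and a format
#' version string.  \code{load_model(save_model(m))} predicts identically
#' to \code{m} on any input.
#'
#' @param model A \code{disorder_model} from [train_predictor()].
#' @param path Archive path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "disorder_model"))
  model$format_version <- MODEL_FORMAT_VERSION
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  model <- tryCatch(readRDS(path),
                    error = function(e) stop("corrupted model archive ", path,
                                             ": ", conditionMessage(e)))
  if (!identical(model$format_version, MODEL_FORMAT_VERSION))
    stop("model archive ", path, ": format version ",
         if (is.null(model$format_version)) "<missing>"
         else model$format_version,
         " does not match ", MODEL_FORMAT_VERSION)
  model
}
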