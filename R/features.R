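# Per-residue 56-feature encoding, sliding-window assembly and [-1,1]
# scaling.  Feature order within each residue block is frozen:
#   AA(1) PP(7) PSSM(20) SS(3) ASA(1) phi/psi(2) MG(1) BG(20) T(1)

#' Encode amino-acid identity as a single number
#'
#' Injective map of the 20 standard one-letter codes onto evenly spaced
#' values in \[-1, +1\] in alphabetical order (A -> -1, Y -> +1, step 2/19).
#'
#' @param residue One-letter residue code(s).
#' @return Numeric vector of the same length.
#' @export
encode_amino_acid <- function(residue) {
  idx <- match(residue, AA_ALPHABET)
  if (anyNA(idx))
    stop("non-standard residue letter: ",
         paste(unique(residue[is.na(idx)]), collapse = ", "))
  -1 + 2 * (idx - 1) / 19
}

#' Physicochemical feature lookup
#'
#' Returns the 7 standardized physicochemical parameters for each residue
#' (see [aa_physchem()]).
#'
#' @param residue One-letter residue code(s).
#' @param table Optional replacement 20 x 7 table (rows named by residue).
#' @return Matrix with one row per residue and 7 columns.
#' @export
phys_chem_features <- function(residue, table = aa_physchem()) {
  idx <- match(residue, rownames(table))
  if (anyNA(idx))
    stop("non-standard residue letter: ",
         paste(unique(residue[is.na(idx)]), collapse = ", "))
  table[idx, , drop = FALSE]
}

#' Normalize a PSSM
#'
#' Divides every log-odds entry by the PSSM normalizing factor 9 (no
#' clamping).
#'
#' @param scores L x 20 log-odds matrix.
#' @return L x 20 numeric matrix.
#' @export
normalize_pssm <- function(scores) {
  stopifnot(is.matrix(scores), ncol(scores) == 20L, all(is.finite(scores)))
  scores / PSSM_NORMALIZER
}

#' Monogram and bigram conservation tables
#'
#' From a normalized PSSM, computes the per-sequence monogram vector and
#' bigram matrix: with \eqn{E_{tj} = \exp(P_{tj})},
#' \eqn{mg_j = \sum_t E_{tj} / e^6} and
#' \eqn{bg_{ij} = \sum_{t<L} E_{ti} E_{(t+1)j} / e^6}.
#' On realistic profile data the pooled values centre near \eqn{e^6} before
#' normalization, so the division recentres them near 1.
#'
#' @param pssm_norm L x 20 normalized PSSM (from [normalize_pssm()]).
#' @return List of class \code{mgbg_tables}: \code{mg} (length-20 vector,
#'   PSSM column order) and \code{bg} (20 x 20 matrix).
#' @export
monogram_bigram <- function(pssm_norm) {
  stopifnot(is.matrix(pssm_norm), ncol(pssm_norm) == 20L)
  L <- nrow(pssm_norm)
  if (L < 2L) stop("bigram undefined for sequences of length < 2")
  E <- exp(pssm_norm)
  mg <- colSums(E) / MGBG_NORMALIZER
  bg <- crossprod(E[-L, , drop = FALSE], E[-1L, , drop = FALSE]) /
    MGBG_NORMALIZER
  names(mg) <- PSSM_COLUMNS
  dimnames(bg) <- list(PSSM_COLUMNS, PSSM_COLUMNS)
  structure(list(mg = mg, bg = bg), class = "mgbg_tables")
}

#' Per-residue monogram/bigram features
#'
#' For a residue of type \code{a}, returns \code{mg[a]} followed by the
#' bigram row \code{bg[a, ]} (21 values).  All residues of one type within
#' a sequence therefore share identical MG/BG features.
#'
#' @param tables \code{mgbg_tables} for the residue's sequence.
#' @param residue One-letter residue code.
#' @return Numeric vector of length 21.
#' @export
residue_mg_bg <- function(tables, residue) {
  stopifnot(inherits(tables, "mgbg_tables"))
  a <- match(residue, PSSM_COLUMNS)
  if (is.na(a)) stop("non-standard residue letter: ", residue)
  c(tables$mg[a], tables$bg[a, ])
}

#' Terminal-position indicator
#'
#' Marks the five residues at each chain end: N-terminal positions get
#' -1.0, -0.8, -0.6, -0.4, -0.2 moving inward, C-terminal positions +1.0,
#' +0.8, +0.6, +0.4, +0.2 moving inward, all other positions 0.  When the
#' two sets overlap (L < 10) the C-terminal assignment wins.
#'
#' @param position 0-based residue position(s).
#' @param L Sequence length.
#' @return Numeric vector of indicator values.
#' @export
terminal_indicator <- function(position, L) {
  if (any(position < 0 | position >= L))
    stop("position out of range [0, ", L - 1, "]")
  val <- numeric(length(position))
  n_side <- position                 # distance from N terminus
  c_side <- L - 1 - position         # distance from C terminus
  val[n_side <= 4] <- -1 + 0.2 * n_side[n_side <= 4]
  val[c_side <= 4] <- 1 - 0.2 * c_side[c_side <= 4]  # C wins on overlap
  val
}

#' Assemble the 56 per-residue features of a chain
#'
#' Concatenates, per residue and in frozen order: amino-acid code (1),
#' physicochemical properties (7), normalized PSSM row (20), predicted
#' helix/sheet/coil probabilities (3), predicted solvent accessibility (1),
#' phi/psi fluctuations (2), monogram (1), bigram row (20) and terminal
#' indicator (1).
#'
#' @param protein An [annotated_protein()].
#' @param pssm The chain's \code{pssm_profile}.
#' @param structural The chain's \code{structural_profile}.
#' @param physchem Optional replacement physicochemical table.
#' @return L x 56 numeric matrix.
#' @export
assemble_features <- function(protein, pssm, structural,
                              physchem = aa_physchem()) {
  stopifnot(inherits(protein, "annotated_protein"))
  if (is.null(pssm)) stop("missing PSSM for chain '", protein$id, "'")
  if (is.null(structural))
    stop("missing structural profile for chain '", protein$id, "'")
  chars <- strsplit(protein$sequence, "")[[1]]
  L <- length(chars)
  if (nrow(pssm$scores) != L)
    stop("chain '", protein$id, "': PSSM has ", nrow(pssm$scores),
         " rows for ", L, " residues")
  if (nrow(structural$tab) != L)
    stop("chain '", protein$id, "': structural profile has ",
         nrow(structural$tab), " rows for ", L, " residues")
  pn <- normalize_pssm(pssm$scores)
  tables <- monogram_bigram(pn)
  a <- match(chars, PSSM_COLUMNS)
  if (anyNA(a))
    stop("chain '", protein$id, "': non-standard residue at position ",
         which(is.na(a))[1])
  out <- cbind(
    encode_amino_acid(chars),
    phys_chem_features(chars, physchem),
    pn,
    structural$tab$p_helix, structural$tab$p_sheet, structural$tab$p_coil,
    structural$tab$asa,
    structural$tab$dphi, structural$tab$dpsi,
    tables$mg[a],
    tables$bg[a, , drop = FALSE],
    terminal_indicator(seq_len(L) - 1L, L)
  )
  stopifnot(ncol(out) == N_FEATURES)
  dimnames(out) <- NULL
  out
}

#' Sliding-window encoding
#'
#' Builds one row per residue by concatenating the 56-feature blocks of the
#' \code{w} residues centred on it; positions beyond either chain end
#' contribute zero blocks.
#'
#' @param blocks L x 56 matrix from [assemble_features()].
#' @param w Odd window size (>= 1).
#' @return L x (w * 56) matrix.
#' @export
window_encode <- function(blocks, w) {
  stopifnot(is.matrix(blocks), ncol(blocks) == N_FEATURES)
  if (w < 1 || w %% 2 == 0) stop("window size must be odd and >= 1, got ", w)
  L <- nrow(blocks)
  h <- (w - 1) / 2
  padded <- rbind(matrix(0, h, N_FEATURES), blocks, matrix(0, h, N_FEATURES))
  cols <- lapply(0:(w - 1), function(o) padded[(1 + o):(L + o), , drop = FALSE])
  do.call(cbind, cols)
}

#' Featurize a whole dataset
#'
#' Runs [assemble_features()] and [window_encode()] on every chain and
#' stacks the rows, keeping a per-row back-reference to chain, position and
#' label.  Unknown-labelled residues are retained as rows (and always as
#' window neighbours); exclude them from training/evaluation by filtering
#' on \code{meta$label}.
#'
#' @param proteins List of [annotated_protein()] objects.
#' @param pssms Named list of \code{pssm_profile}s (names = chain ids).
#' @param structurals Named list of \code{structural_profile}s.
#' @param window Odd window size.
#' @return List with \code{x} (matrix, one row per residue) and \code{meta}
#'   (data frame: \code{id}, \code{pos} 1-based, \code{residue},
#'   \code{label}).
#' @export
featurize_dataset <- function(proteins, pssms, structurals, window = 21L) {
  parts <- lapply(proteins, function(p) {
    blocks <- assemble_features(p, pssms[[p$id]], structurals[[p$id]])
    window_encode(blocks, window)
  })
  meta <- do.call(rbind, lapply(proteins, function(p) {
    data.frame(id = p$id, pos = seq_len(nchar(p$sequence)),
               residue = strsplit(p$sequence, "")[[1]],
               label = p$labels, stringsAsFactors = FALSE)
  }))
  rownames(meta) <- NULL
  list(x = do.call(rbind, parts), meta = meta)
}

#' Fit / apply a per-column [-1, +1] scaler
#'
#' \code{fit_scaler} records per-column extrema of the training matrix;
#' \code{apply_scaler} maps \code{x' = -1 + 2 (x - min) / (max - min)}.
#' Constant columns map to 0.  Unseen data may exceed \[-1, +1\] and is not
#' clipped.
#'
#' @param train Training feature matrix (fit on training rows only).
#' @return \code{fit_scaler}: object of class \code{scaler_params};
#'   \code{apply_scaler}: the rescaled matrix.
#' @export
fit_scaler <- function(train) {
  stopifnot(is.matrix(train))
  if (nrow(train) < 1L) stop("cannot fit scaler on an empty matrix")
  structure(list(min = apply(train, 2, min), max = apply(train, 2, max)),
            class = "scaler_params")
}

#' @rdname fit_scaler
#' @param params A \code{scaler_params} object.
#' @param x Matrix to rescale (same column count as the training matrix).
#' @export
apply_scaler <- function(params, x) {
  stopifnot(inherits(params, "scaler_params"), is.matrix(x))
  if (ncol(x) != length(params$min))
    stop("column count ", ncol(x), " does not match scaler (",
         length(params$min), ")")
  rng <- params$max - params$min
  const <- rng == 0
  rng[const] <- 1
  out <- sweep(sweep(x, 2, params$min), 2, rng / 2, "/") - 1
  out[, const] <- 0
  out
}

#' Export a labelled feature matrix in sparse SVM-tool format
#'
#' Writes the \code{<label> <index>:<value>} dialect used by common SVM
#' command-line tools: label +1 for disorder, -1 for order; rows with
#' unknown labels are excluded; zero entries are omitted.
#'
#' @param x Feature matrix.
#' @param labels Per-row labels over \code{c("O","D","U")}.
#' @param path Output path.
#' @export
write_svm_format <- function(x, labels, path) {
  stopifnot(nrow(x) == length(labels))
  keep <- labels != "U"
  con <- file(path, "w"); on.exit(close(con))
  for (i in which(keep)) {
    nz <- which(x[i, ] != 0)
    writeLines(paste(if (labels[i] == "D") "+1" else "-1",
                     paste0(nz, ":", sprintf("%g", x[i, nz]),
                            collapse = " ")), con)
  }
  invisible(path)
}
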