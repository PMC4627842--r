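# Seeded synthetic datasets with the statistical structure the predictor
# assumes: chains with alternating ordered/disordered runs, disorder-prone
# composition shifts, state-dependent PSSM column statistics, and coil
# probability / exposure elevated in disordered segments.  The generator
# makes the whole pipeline buildable and testable without any download.

# composition of ordered segments: approximate background frequencies
COMP_ORDER <- c(A = 0.083, C = 0.014, D = 0.055, E = 0.067, F = 0.039,
                G = 0.071, H = 0.023, I = 0.059, K = 0.058, L = 0.097,
                M = 0.024, N = 0.041, P = 0.047, Q = 0.039, R = 0.055,
                S = 0.066, T = 0.053, V = 0.069, W = 0.011, Y = 0.029)

# disorder-prone target: enriched in D,G,S,E,K,P, depleted in hydrophobics
COMP_DISORDER <- c(A = 0.070, C = 0.004, D = 0.090, E = 0.110, F = 0.015,
                   G = 0.100, H = 0.020, I = 0.020, K = 0.100, L = 0.040,
                   M = 0.015, N = 0.040, P = 0.100, Q = 0.050, R = 0.050,
                   S = 0.110, T = 0.050, V = 0.030, W = 0.004, Y = 0.012)

DISORDER_PRONE <- c("D", "G", "S", "E", "K", "P")

#' Configuration for the synthetic dataset generator
#'
#' Defaults describe the emulated study conditions: ~24\% disorder
#' prevalence, 70\% of disordered regions short (<= 30 residues) and 30\%
#' long, chains of mean length 400, and 5\% unknown-labelled residues to
#' exercise the exclusion logic.  \code{signal} in \[0,1\] scales every
#' state-dependent shift (composition, PSSM means, coil probability,
#' accessibility, torsion fluctuations); at 0 the two states are
#' statistically identical.
#'
#' @param n_chains Number of chains.
#' @param length_mean,length_sd Chain-length distribution (normal,
#'   truncated at 30).
#' @param prevalence Target disordered fraction in (0,1).
#' @param short_frac Fraction of disordered regions drawn short (4-30
#'   residues); the rest are long (31-90).
#' @param signal State-separation strength in \[0,1\].
#' @param unknown_rate Fraction of residues relabelled unknown.
#' @param seed Integer seed (mandatory).
#' @return List of class \code{simulation_config}.
#' @export
simulation_config <- function(n_chains = 50L, length_mean = 400,
                              length_sd = 100, prevalence = 0.24,
                              short_frac = 0.7, signal = 1,
                              unknown_rate = 0.05, seed) {
  if (missing(seed)) stop("a seed is mandatory for simulation_config")
  stopifnot(n_chains >= 1, length_mean >= 30,
            prevalence > 0, prevalence < 1,
            short_frac >= 0, short_frac <= 1,
            signal >= 0, signal <= 1,
            unknown_rate >= 0, unknown_rate < 1)
  structure(list(n_chains = as.integer(n_chains),
                 length_mean = length_mean, length_sd = length_sd,
                 prevalence = prevalence, short_frac = short_frac,
                 signal = signal, unknown_rate = unknown_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Alternating O/D run labels for one chain of length L.
sim_state_runs <- function(L, cfg) {
  # expected disordered-region length under the short/long mix
  e_dis <- cfg$short_frac * mean(4:30) + (1 - cfg$short_frac) * mean(31:90)
  mean_ord <- max(6, e_dis * (1 - cfg$prevalence) / cfg$prevalence)
  state <- character(0)
  cur <- if (stats::runif(1) < cfg$prevalence) "D" else "O"
  while (length(state) < L) {
    len <- if (cur == "D") {
      if (stats::runif(1) < cfg$short_frac) sample(4:30, 1)
      else sample(31:90, 1)
    } else {
      5 + stats::rgeom(1, 1 / (mean_ord - 5))
    }
    state <- c(state, rep(cur, len))
    cur <- if (cur == "D") "O" else "D"
  }
  state[seq_len(L)]
}

# State-dependent PSSM row for one residue (raw integer log-odds in ±13).
sim_pssm_rows <- function(chars, state, signal) {
  L <- length(chars)
  scores <- matrix(stats::rnorm(L * 20, mean = -2, sd = 2), L, 20)
  own <- match(chars, PSSM_COLUMNS)
  dis <- state == "D"
  # conservation of the native residue, weaker in disordered segments
  scores[cbind(seq_len(L), own)] <-
    stats::rnorm(L, mean = 4 - 3 * signal * dis, sd = 2)
  # disorder-prone columns drift up inside disordered segments
  prone <- match(DISORDER_PRONE, PSSM_COLUMNS)
  if (any(dis))
    scores[dis, prone] <- scores[dis, prone] + 2 * signal
  scores <- round(clamp(scores, -13, 13))
  colnames(scores) <- PSSM_COLUMNS
  scores
}

#' Generate a synthetic disorder dataset
#'
#' Builds \code{cfg$n_chains} chains with alternating ordered/disordered
#' runs hitting the configured prevalence and short/long mix in
#' expectation.  Disordered residues are drawn from a composition enriched
#' in D, G, S, E, K, P; PSSM log-odds get state-dependent means; coil
#' probability, solvent accessibility and torsion fluctuations are elevated
#' in disordered segments, all proportionally to \code{cfg$signal}.  Fully
#' reproducible from \code{cfg$seed}.
#'
#' @param cfg A [simulation_config()].
#' @return List of class \code{synthetic_dataset} with \code{proteins},
#'   \code{pssms}, \code{structurals} (all named by chain id) and
#'   \code{config}.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  s <- cfg$signal
  comp_dis <- (1 - s) * COMP_ORDER + s * COMP_DISORDER
  with_seed(cfg$seed, {
    proteins <- list(); pssms <- list(); structurals <- list()
    for (ci in seq_len(cfg$n_chains)) {
      id <- sprintf("syn%03d", ci)
      L <- max(30L, round(stats::rnorm(1, cfg$length_mean, cfg$length_sd)))
      state <- sim_state_runs(L, cfg)
      dis <- state == "D"
      chars <- character(L)
      if (any(!dis))
        chars[!dis] <- sample(AA_ALPHABET, sum(!dis), replace = TRUE,
                              prob = COMP_ORDER)
      if (any(dis))
        chars[dis] <- sample(AA_ALPHABET, sum(dis), replace = TRUE,
                             prob = comp_dis)
      scores <- sim_pssm_rows(chars, state, s)

      p_coil <- clamp(stats::rnorm(L, 0.30 + 0.45 * s * dis, 0.08),
                      0.02, 0.96)
      u <- stats::runif(L)
      p_helix <- (1 - p_coil) * u
      p_sheet <- 1 - p_coil - p_helix
      asa <- clamp(stats::rnorm(L, 0.22 + 0.35 * s * dis, 0.10), 0, 1)
      dphi <- abs(stats::rnorm(L, 0, 8 + 12 * s * dis))
      dpsi <- abs(stats::rnorm(L, 0, 8 + 12 * s * dis))

      labels <- state
      if (cfg$unknown_rate > 0) {
        u_mask <- stats::runif(L) < cfg$unknown_rate
        labels[u_mask] <- "U"
      }

      proteins[[id]] <- annotated_protein(id, paste(chars, collapse = ""),
                                          labels)
      pssms[[id]] <- structure(list(id = id, scores = scores,
                                    residues = chars),
                               class = "pssm_profile")
      structurals[[id]] <- structural_profile(
        id, data.frame(p_helix = p_helix, p_sheet = p_sheet,
                       p_coil = p_coil, asa = asa,
                       dphi = dphi, dpsi = dpsi))
    }
    structure(list(proteins = proteins, pssms = pssms,
                   structurals = structurals, config = cfg),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  labs <- unlist(lapply(x$proteins, `[[`, "labels"))
  cat(sprintf(paste0("<synthetic_dataset> %d chains, %d residues ",
                     "(%.1f%% D, %.1f%% U), signal %.2f, seed %d\n"),
              length(x$proteins), length(labs),
              100 * mean(labs == "D"), 100 * mean(labs == "U"),
              x$config$signal, x$config$seed))
  invisible(x)
}

#' Write a synthetic dataset as an on-disk fixture bundle
#'
#' Emits one FASTA file (\code{sequences.fasta}) plus, per chain,
#' \code{<id>.pssm} (PSI-BLAST-style ASCII matrix), \code{<id>.profile}
#' (structural profile) and \code{<id>.annot} (three-state annotation), in
#' the dialects the package readers consume.  Regeneration from the same
#' config yields byte-identical files.
#'
#' @param dataset A \code{synthetic_dataset}.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_fixture_bundle <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, "sequences.fasta")
  con <- file(fasta, "w")
  for (p in dataset$proteins)
    writeLines(c(paste0(">", p$id), p$sequence), con)
  close(con)
  for (p in dataset$proteins) {
    id <- p$id
    chars <- strsplit(p$sequence, "")[[1]]
    scores <- dataset$pssms[[id]]$scores
    lines <- c("",
               "Last position-specific scoring matrix computed",
               paste0("      ", paste(sprintf("%3s", PSSM_COLUMNS),
                                      collapse = " ")),
               vapply(seq_along(chars), function(i)
                 paste0(sprintf("%5d %s ", i, chars[i]),
                        paste(sprintf("%3d", scores[i, ]), collapse = " ")),
                 ""))
    writeLines(lines, file.path(dir, paste0(id, ".pssm")))
    tab <- dataset$structurals[[id]]$tab
    writeLines(sprintf("%d\t%s\t%.4f\t%.4f\t%.4f\t%.4f\t%.4f\t%.4f",
                       seq_along(chars), chars, tab$p_helix, tab$p_sheet,
                       tab$p_coil, tab$asa, tab$dphi, tab$dpsi),
               file.path(dir, paste0(id, ".profile")))
    writeLines(sprintf("%d\t%s\t%s", seq_along(chars), chars, p$labels),
               file.path(dir, paste0(id, ".annot")))
  }
  invisible(dir)
}

#' Read a fixture bundle back into a dataset
#'
#' Inverse of [write_fixture_bundle()]: reads the FASTA and the per-chain
#' PSSM, structural-profile and annotation files from a directory.
#'
#' @param dir Bundle directory.
#' @return List with \code{proteins}, \code{pssms}, \code{structurals}.
#' @export
read_fixture_bundle <- function(dir) {
  seqs <- read_fasta(file.path(dir, "sequences.fasta"))
  proteins <- list(); pssms <- list(); structurals <- list()
  for (id in names(seqs)) {
    seq <- seqs[[id]]
    annot_path <- file.path(dir, paste0(id, ".annot"))
    labels <- if (file.exists(annot_path)) read_annotation(annot_path, seq)
              else rep("U", nchar(seq))
    proteins[[id]] <- annotated_protein(id, seq, labels)
    pssms[[id]] <- read_pssm(file.path(dir, paste0(id, ".pssm")), seq,
                             id = id)
    structurals[[id]] <- read_structural_profile(
      file.path(dir, paste0(id, ".profile")), seq, id = id)
  }
  list(proteins = proteins, pssms = pssms, structurals = structurals)
}
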