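#' @title Drug encoding: circular fingerprints and the rare-drug filter
#' @name chem
#' @description Drugs enter the model as fixed-length (default 2048-bit)
#'   circular substructure fingerprints computed from SMILES. SMILES are
#'   parsed with OpenBabel (via ChemmineOB/ChemmineR); the iterative
#'   neighborhood hashing and folding are implemented here and documented in
#'   the methods vignette. A support filter removes drugs with too few
#'   training observations, the condition under which networks memorize a
#'   single patient's outcome instead of generalizing.
NULL

.element_z <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12, Al = 13,
  Si = 14, P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Cr = 24, Mn = 25,
  Fe = 26, Co = 27, Ni = 28, Cu = 29, Zn = 30, As = 33, Se = 34, Br = 35,
  Mo = 42, Ru = 44, Rh = 45, Pd = 46, Ag = 47, Cd = 48, Sn = 50, Sb = 51,
  I = 53, Pt = 78, Au = 79, Hg = 80, Pb = 82, Bi = 83
)

# 31-bit polynomial hash over a nonnegative-shifted integer tuple.
# The same recurrence is what an independent oracle must reproduce.
.hash_ints <- function(xs) {
  h <- 17
  for (x in xs) h <- (h * 1000003 + (x + 128)) %% 2147483647
  h
}

# Parse one SMILES into a heavy-atom molecular graph using OpenBabel with
# explicit hydrogens added. Returns list(z, charge, n_h, degree, valence2,
# neighbors) over heavy atoms; valence2 = twice the sum of bond orders
# (including bonds to H), so aromatic order 4 can count as 1.5 exactly.
.smiles_to_graph <- function(smiles, name = smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles)) {
    stop("invalid SMILES for drug ", name)
  }
  sdf_txt <- tryCatch(
    ChemmineOB::convertFormat(
      "SMI", "SDF", paste0(smiles, "\t", name, "\n"),
      options = data.frame(names = "h", args = "")
    ),
    error = function(e) ""
  )
  lines <- strsplit(sdf_txt, "\n", fixed = TRUE)[[1L]]
  if (length(lines) < 5L) stop("could not parse SMILES for drug ", name)
  sdf_file <- tempfile(fileext = ".sdf")
  on.exit(unlink(sdf_file), add = TRUE)
  writeLines(lines, sdf_file)
  sdfset <- tryCatch(ChemmineR::read.SDFset(sdf_file),
                     error = function(e) NULL)
  if (is.null(sdfset) || length(sdfset) < 1L) {
    stop("could not parse SMILES for drug ", name)
  }
  ab <- ChemmineR::atomblock(sdfset[[1L]])
  bb <- ChemmineR::bondblock(sdfset[[1L]])
  n_atoms <- nrow(ab)
  if (is.null(n_atoms) || n_atoms < 1L) {
    stop("could not parse SMILES for drug ", name)
  }
  elem <- sub("_.*$", "", rownames(ab))
  z <- unname(.element_z[elem])
  if (anyNA(z)) {
    stop("unsupported element '", elem[which(is.na(z))[1L]],
         "' in drug ", name)
  }
  charge <- integer(n_atoms)
  n_bonds <- if (is.null(nrow(bb))) 0L else nrow(bb)
  bonds <- matrix(0L, nrow = max(n_bonds, 0L), ncol = 3L)
  if (n_bonds > 0L) bonds[, 1L:3L] <- as.integer(as.matrix(bb[, 1L:3L]))
  for (chg_line in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", chg_line)),
                             "\\s+")[[1L]])
    n <- f[1L]
    for (i in seq_len(n)) {
      charge[f[2L * i]] <- f[2L * i + 1L]
    }
  }
  heavy <- which(z > 1L)
  idx_of <- integer(n_atoms)
  idx_of[heavy] <- seq_along(heavy)
  n_h <- integer(length(heavy))
  degree <- integer(length(heavy))
  valence2 <- integer(length(heavy))
  neighbors <- vector("list", length(heavy))
  for (i in seq_along(neighbors)) neighbors[[i]] <- integer(0)
  if (n_bonds > 0L) {
    for (b in seq_len(n_bonds)) {
      a1 <- bonds[b, 1L]; a2 <- bonds[b, 2L]; o <- bonds[b, 3L]
      o2 <- if (o == 4L) 3L else 2L * o # aromatic counts as 1.5
      for (pair in list(c(a1, a2), c(a2, a1))) {
        if (z[pair[1L]] > 1L) {
          i <- idx_of[pair[1L]]
          valence2[i] <- valence2[i] + o2
          if (z[pair[2L]] > 1L) {
            degree[i] <- degree[i] + 1L
            neighbors[[i]] <- c(neighbors[[i]], idx_of[pair[2L]])
          } else {
            n_h[i] <- n_h[i] + 1L
          }
        }
      }
    }
  }
  list(z = z[heavy], charge = charge[heavy], n_h = n_h, degree = degree,
       valence2 = valence2, neighbors = neighbors)
}

#' Circular fingerprint of a molecule from its SMILES
#'
#' Morgan-style extended-connectivity fingerprint: each heavy atom starts
#' from an invariant hash of (atomic number, heavy degree, attached
#' hydrogens, formal charge, total valence), and for each radius step the
#' invariant is rehashed with the sorted invariants of its neighbors. All
#' invariants from radius 0 up to \code{radius} are folded into
#' \code{n_bits} bits by modulus. Using the total valence rather than
#' per-bond orders makes the result independent of the kekulization an
#' input SMILES happens to use.
#'
#' @param smiles A SMILES string.
#' @param n_bits Fingerprint length in bits (default 2048).
#' @param radius Neighborhood radius (default 2, the common ECFP4-equivalent
#'   setting).
#' @param name Drug name used in error messages.
#' @return Integer vector of 0/1 of length \code{n_bits}.
#' @export
smiles_to_fingerprint <- function(smiles, n_bits = 2048L, radius = 2L,
                                  name = smiles) {
  if (!is.numeric(n_bits) || n_bits <= 0) stop("n_bits must be positive")
  if (!is.numeric(radius) || radius < 0) stop("radius must be nonnegative")
  n_bits <- as.integer(n_bits)
  key <- paste(smiles, n_bits, radius, sep = "\r")
  cached <- .fp_cache[[key]]
  if (!is.null(cached)) return(cached)
  g <- .smiles_to_graph(smiles, name)
  n <- length(g$z)
  inv <- vapply(seq_len(n), function(i) {
    .hash_ints(c(g$z[i], g$degree[i], g$n_h[i], g$charge[i], g$valence2[i]))
  }, numeric(1))
  ids <- inv
  if (radius >= 1L) {
    # an atom emits a new identifier only while its neighborhood ball is
    # still growing (ECFP convention: terminal atoms stop at radius 0)
    ball <- lapply(seq_len(n), function(i) i)
    for (r in seq_len(radius)) {
      inv_new <- vapply(seq_len(n), function(i) {
        .hash_ints(c(r, inv[i], sort(inv[g$neighbors[[i]]])))
      }, numeric(1))
      ball_new <- lapply(seq_len(n), function(i) {
        unique(c(ball[[i]], unlist(ball[g$neighbors[[i]]])))
      })
      grew <- vapply(seq_len(n), function(i) {
        length(ball_new[[i]]) > length(ball[[i]])
      }, logical(1))
      inv <- inv_new
      ball <- ball_new
      ids <- c(ids, inv[grew])
    }
  }
  fp <- integer(n_bits)
  fp[unique(ids %% n_bits) + 1L] <- 1L
  .fp_cache[[key]] <- fp
  fp
}

# fingerprints are pure functions of (smiles, n_bits, radius); memoized
.fp_cache <- new.env(parent = emptyenv())

#' Read a drug library and fingerprint every compound
#'
#' @param path TSV with columns \code{name}, \code{smiles}; or a data frame
#'   with those columns.
#' @param n_bits,radius Fingerprint settings, see [smiles_to_fingerprint()].
#' @return A list with \code{table} (the input data frame) and
#'   \code{fingerprints}, a drugs-by-bits 0/1 matrix with drug names as row
#'   names, rows ordered by drug name.
#' @export
read_drug_library <- function(path, n_bits = 2048L, radius = 2L) {
  tbl <- if (is.data.frame(path)) path else
    utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "smiles") %in% names(tbl))) {
    stop("drug library must have columns name, smiles")
  }
  if (anyDuplicated(tbl$name)) stop("duplicate drug names in library")
  tbl <- tbl[order(tbl$name), , drop = FALSE]
  fps <- matrix(0L, nrow = nrow(tbl), ncol = as.integer(n_bits),
                dimnames = list(tbl$name, NULL))
  for (i in seq_len(nrow(tbl))) {
    fps[i, ] <- smiles_to_fingerprint(tbl$smiles[i], n_bits, radius,
                                      name = tbl$name[i])
  }
  list(table = tbl, fingerprints = fps)
}

#' Remove drugs with insufficient training support
#'
#' A drug is kept iff it has at least \code{min_support} (patient, drug)
#' data points in the training partition; pairs of removed drugs are
#' dropped from every partition. This defeats the memorization effect in
#' which the network reproduces the one training patient's survival for a
#' rarely seen drug.
#'
#' @param pairs Data frame with columns \code{patient_id}, \code{drug}, and
#'   optionally \code{fold} (\code{"train"}/\code{"validation"}); if
#'   \code{fold} is absent all rows count as training.
#' @param min_support Minimum number of training data points (default 5).
#' @return List with \code{kept} (surviving rows of \code{pairs}) and
#'   \code{removed} (data frame of drug, training support).
#' @export
filter_rare_drugs <- function(pairs, min_support = 5L) {
  if (!is.numeric(min_support) || min_support < 1) {
    stop("min_support must be a positive integer")
  }
  if (!nrow(pairs)) {
    return(list(kept = pairs,
                removed = data.frame(drug = character(0),
                                     support = integer(0))))
  }
  train_rows <- if ("fold" %in% names(pairs)) pairs$fold == "train" else
    rep(TRUE, nrow(pairs))
  support <- table(factor(pairs$drug[train_rows],
                          levels = sort(unique(pairs$drug))))
  removed_drugs <- names(support)[support < min_support]
  removed <- data.frame(drug = removed_drugs,
                        support = as.integer(support[removed_drugs]),
                        stringsAsFactors = FALSE)
  if (nrow(removed)) {
    message("removing ", nrow(removed), " drug(s) with training support < ",
            min_support, ": ", paste(removed$drug, collapse = ", "))
  }
  list(kept = pairs[!(pairs$drug %in% removed_drugs), , drop = FALSE],
       removed = removed)
}
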