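## Synthetic spectra libraries with exactly known structural similarity.
##
## Molecules are ordered chains of moieties drawn from a small alphabet of
## realistic residue masses; an analog family shares a scaffold chain and
## differs by a few moiety substitutions (including the classic +15.99 Da
## oxygen and +14.02 Da methylene modifications) or by an adjacent
## transposition (a constitutional-isomer stand-in with identical moiety
## content). A spectrum is the chain's prefix-sum fragment series plus a
## protonated precursor, with multiplicative intensity noise, occasional
## fragment dropout and spurious peaks. Ground-truth structural
## similarity is the multiset Jaccard index of moiety masses - exactly
## computable, symmetric, 1 iff the multisets coincide.

PROTON_MASS <- 1.01

## Residue-like moiety masses (Da, 2 dp) plus small modification deltas.
#' @rdname generate_library
#' @export
moiety_alphabet <- function() {
  c(gly = 57.02, ala = 71.04, ser = 87.03, pro = 97.05, val = 99.07,
    thr = 101.05, leu = 113.08, asn = 114.04, asp = 115.03, gln = 128.06,
    lys = 128.09, glu = 129.04, met = 131.04, phe = 147.07)
}

moiety_deltas <- function() c(O = 15.99, CH2 = 14.02, H2O = 18.01, H2 = 2.01)

#' Noise configuration for synthetic spectra
#'
#' @param intensity_cv Multiplicative log-normal intensity noise
#'   (coefficient of variation scale).
#' @param dropout_rate Probability that a non-terminal fragment peak is
#'   missing from a spectrum.
#' @param spurious_rate Expected number of spurious (unrelated) peaks per
#'   spectrum, at 1-10% relative intensity.
#' @return A `noise_config` list.
#' @export
noise_config <- function(intensity_cv = 0.3, dropout_rate = 0.05,
                         spurious_rate = 0.5) {
  structure(list(intensity_cv = intensity_cv, dropout_rate = dropout_rate,
                 spurious_rate = spurious_rate), class = "noise_config")
}

#' Generate a synthetic spectra library
#'
#' Samples analog families of chain molecules and one or more noisy
#' fragment spectra per molecule (see the package vignette for the
#' generative model). Spectra are emitted raw; run
#' [preprocess_spectra()] before encoding. Molecules are assigned to
#' train/validation/test splits (70/15/15) disjointly by molecule.
#'
#' @param n_molecules Number of molecules (>= 2).
#' @param spectra_per_molecule Spectra per molecule.
#' @param noise A [noise_config()].
#' @param seed Integer seed; the library is fully determined by it.
#' @return An object of class `synthetic_library`: a list with tibbles
#'   `molecules` (`molecule_id`, `family_id`, `moieties` list column,
#'   `total_mass`, `split`) and `spectra` (spectra tibble whose
#'   `structure_key` is the molecule id).
#' @export
generate_library <- function(n_molecules = 200L, spectra_per_molecule = 1L,
                             noise = noise_config(), seed = 0L) {
  stopifnot(n_molecules >= 2L, spectra_per_molecule >= 1L)
  alphabet <- moiety_alphabet()
  deltas <- moiety_deltas()
  withr::with_seed(as.integer(seed), {
    mols <- list()
    mol_fam <- integer(0)
    fam <- 0L
    while (length(mols) < n_molecules) {
      fam <- fam + 1L
      L <- sample(5:9, 1L)
      scaffold <- sample(alphabet, L, replace = TRUE)
      while (sum(scaffold) > 950) scaffold <- sample(alphabet, L, replace = TRUE)
      fam_size <- min(sample(4:10, 1L), n_molecules - length(mols))
      members <- list(scaffold)
      if (fam_size > 1L) {
        for (v in seq_len(fam_size - 1L)) {
          kind <- sample(c("edit1", "edit2", "edit3", "isomer"), 1L,
                         prob = c(0.45, 0.2, 0.1, 0.25))
          m <- scaffold
          if (kind == "isomer" && L >= 2L) {
            pos <- sample(L - 1L, 1L)
            m[c(pos, pos + 1L)] <- m[c(pos + 1L, pos)]
          } else {
            d <- switch(kind, edit1 = 1L, edit2 = 2L, 3L)
            pos <- sample(L, min(d, L))
            for (p in pos) {
              if (runif(1) < 0.5) {
                m[p] <- round(m[p] + sample(deltas, 1L), 2)
              } else {
                m[p] <- sample(alphabet, 1L)
              }
            }
          }
          if (sum(m) <= 990) members <- c(members, list(m))
        }
      }
      take <- seq_len(min(length(members), n_molecules - length(mols)))
      mols <- c(mols, members[take])
      mol_fam <- c(mol_fam, rep(fam, length(take)))
    }
    molecules <- tibble::tibble(
      molecule_id = sprintf("M%04d", seq_along(mols)),
      family_id = sprintf("F%03d", mol_fam),
      moieties = lapply(mols, function(m) round(unname(m), 2)),
      total_mass = vapply(mols, function(m) round(sum(m), 2), double(1))
    )
    ## splits: shuffle molecules, 70/15/15
    n <- nrow(molecules)
    ord <- sample.int(n)
    n_val <- max(1L, round(0.15 * n))
    n_test <- max(1L, round(0.15 * n))
    split <- rep("train", n)
    split[ord[seq_len(n_val)]] <- "validation"
    split[ord[n_val + seq_len(n_test)]] <- "test"
    molecules$split <- split

    spectra <- vector("list", n * spectra_per_molecule)
    k <- 0L
    for (i in seq_len(n)) {
      for (r in seq_len(spectra_per_molecule)) {
        k <- k + 1L
        spectra[[k]] <- synth_spectrum(
          molecules$moieties[[i]], molecules$molecule_id[i], r, noise)
      }
    }
    lib <- list(molecules = molecules,
                spectra = as_ms2_spectra(dplyr::bind_rows(spectra)))
    class(lib) <- "synthetic_library"
    lib
  })
}

## One noisy spectrum for a moiety chain: prefix-sum fragments + precursor.
synth_spectrum <- function(moieties, molecule_id, replicate, noise) {
  L <- length(moieties)
  frag_mz <- round(cumsum(moieties) + PROTON_MASS, 2)
  precursor <- frag_mz[L]
  base <- exp(rnorm(L, mean = 0, sd = 0.4)) * 100
  base <- base * exp(rnorm(L, sd = noise$intensity_cv))
  keep <- c(runif(L - 1L) >= noise$dropout_rate, TRUE)
  if (!any(keep)) keep[L] <- TRUE
  mz <- frag_mz[keep]
  int <- base[keep]
  n_spur <- stats::rpois(1L, noise$spurious_rate)
  if (n_spur > 0L) {
    smz <- round(runif(n_spur, 20, max(precursor - 20, 30)), 2)
    smz <- setdiff(smz, mz)
    if (length(smz)) {
      mz <- c(mz, smz)
      int <- c(int, runif(length(smz), 0.01, 0.1) * max(int))
    }
  }
  o <- order(mz)
  tibble::tibble(
    spectrum_id = sprintf("%s_s%02d", molecule_id, replicate),
    precursor_mz = precursor,
    structure_key = molecule_id,
    peaks = list(tibble::tibble(mz = mz[o], intensity = int[o]))
  )
}

## Deterministic, noise-free spectrum for a moiety chain (used for
## controlled fixtures): prefix-sum fragments with a flat intensity
## ladder, protonated precursor.
synth_spectrum_clean <- function(moieties, molecule_id = "mol") {
  L <- length(moieties)
  mz <- round(cumsum(moieties) + PROTON_MASS, 2)
  list(peaks = tibble::tibble(mz = mz,
                              intensity = seq(100, 60, length.out = L)),
       precursor_mz = mz[L],
       spectrum_id = molecule_id)
}

#' Ground-truth structural similarity of synthetic molecules
#'
#' Multiset Jaccard index of the two moiety-mass multisets:
#' `sum(min(count_a, count_b)) / sum(max(count_a, count_b))`.
#'
#' @param a,b Numeric vectors of moiety masses (order irrelevant).
#' @return Similarity in `[0, 1]`; 1 iff the multisets are equal.
#' @export
true_similarity <- function(a, b) {
  masses <- sort(unique(c(a, b)))
  ca <- tabulate(match(a, masses), length(masses))
  cb <- tabulate(match(b, masses), length(masses))
  denom <- sum(pmax(ca, cb))
  if (denom == 0L) return(0)
  sum(pmin(ca, cb)) / denom
}

#' All-pairs ground-truth similarity matrix of a synthetic library
#'
#' @param library A [generate_library()] result.
#' @param molecule_ids Optional subset/order of molecule ids.
#' @return A symmetric matrix with molecule ids as dimnames.
#' @export
similarity_matrix <- function(library, molecule_ids = NULL) {
  stopifnot(inherits(library, "synthetic_library"))
  mols <- library$molecules
  if (!is.null(molecule_ids)) {
    mols <- mols[match(molecule_ids, mols$molecule_id), ]
  }
  n <- nrow(mols)
  S <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      S[i, j] <- S[j, i] <- true_similarity(mols$moieties[[i]], mols$moieties[[j]])
    }
  }
  dimnames(S) <- list(mols$molecule_id, mols$molecule_id)
  S
}

#' @export
print.synthetic_library <- function(x, ...) {
  cat(sprintf("<synthetic_library> %d molecules, %d spectra (train/val/test: %s)\n",
              nrow(x$molecules), nrow(x$spectra),
              paste(table(x$molecules$split)[c("train", "validation", "test")],
                    collapse = "/")))
  invisible(x)
}
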