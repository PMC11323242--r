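# Molecule parsing, canonicalization, circular fingerprints, descriptors and
# the Tanimoto distance. OpenBabel (via ChemmineOB) does all chemistry
# perception; fingerprints are computed here from the kekulized molfile graph
# so that the radius and folded width are configurable and the per-atom
# substructure keys remain available to the idiosyncrasy filter.

HASH_MOD <- 2147483629  # largest prime < 2^31; all keys live in [0, HASH_MOD)

#' Fingerprint configuration
#'
#' Settings for the binary folded circular (Morgan-style) fingerprint used
#' throughout the package: atom environments of radius 0..`radius` are hashed
#' to integer keys and folded onto `n_bits` bits.
#'
#' @param radius Non-negative integer, maximum neighborhood radius in bonds.
#'   The default 2 corresponds to ECFP4-class fingerprints, the de-facto
#'   community standard for similarity work.
#' @param n_bits Positive integer, folded fingerprint width. Must be a power
#'   of two (folding convention).
#' @param use_counts Logical; if `TRUE` fingerprints carry key multiplicities
#'   and the Tanimoto distance uses the count (min/max) form. The default
#'   `FALSE` gives binary fingerprints, the package's reference setting.
#' @return An object of class `fingerprint_config`.
#' @examples
#' cfg <- fingerprint_config(radius = 2, n_bits = 1024)
#' @export
fingerprint_config <- function(radius = 2L, n_bits = 2048L, use_counts = FALSE) {
  radius <- as.integer(radius)
  n_bits <- as.integer(n_bits)
  stopifnot(length(radius) == 1L, radius >= 0L, length(n_bits) == 1L, n_bits >= 1L)
  if (bitwAnd(n_bits, n_bits - 1L) != 0L)
    stop("n_bits must be a power of two (folding convention), got ", n_bits)
  structure(list(radius = radius, n_bits = n_bits, use_counts = isTRUE(use_counts)),
            class = "fingerprint_config")
}

# ---- molfile graph ----------------------------------------------------------

# Parse a single V2000 molfile text block into a minimal graph:
# elements, bond lists (1-based atom indices), bond orders, formal charges.
# Fixed-width fields are used so >99-atom molecules parse correctly.
parse_molfile <- function(txt) {
  ln <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(ln) < 4L) return(NULL)
  na <- suppressWarnings(as.integer(substr(ln[4L], 1L, 3L)))
  nb <- suppressWarnings(as.integer(substr(ln[4L], 4L, 6L)))
  if (is.na(na) || is.na(nb) || na < 1L) return(NULL)
  at <- ln[5L:(4L + na)]
  elem <- trimws(substr(at, 32L, 34L))
  if (nb > 0L) {
    bl <- ln[(5L + na):(4L + na + nb)]
    b1 <- as.integer(substr(bl, 1L, 3L))
    b2 <- as.integer(substr(bl, 4L, 6L))
    bo <- as.integer(substr(bl, 7L, 9L))
  } else {
    b1 <- b2 <- bo <- integer(0)
  }
  chg <- integer(na)
  for (l in ln[startsWith(ln, "M  CHG")]) {
    v <- suppressWarnings(as.integer(strsplit(trimws(substring(l, 7L)), "\\s+")[[1]]))
    k <- v[1L]
    for (j in seq_len(k)) chg[v[2L * j]] <- v[2L * j + 1L]
  }
  list(elem = elem, b1 = b1, b2 = b2, bo = bo, charge = chg, n = na,
       lines = ln, n_atoms = na, n_bonds = nb)
}

ATOMIC_NUMBER <- local({
  sym <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg",
           "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca", "As", "Se", "Br", "I",
           "Sn", "Zn", "Fe", "Cu")
  z <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19,
         20, 33, 34, 35, 53, 50, 30, 26, 29)
  stats::setNames(as.integer(z), sym)
})

hash_mix <- function(h, x) (h * 31 + x) %% HASH_MOD

# Atom-centered circular substructure keys, radii 0..radius, one integer key
# per (atom, radius); returned as the concatenation over radii (duplicates
# kept so callers can count multiplicities). The radius-0 invariant combines
# atomic number, heavy-atom degree, bond-order sum and formal charge; each
# iteration hashes the sorted (bond order, neighbor key) list into the
# center's previous key, exactly the Morgan update.
circular_keys <- function(g, radius = 2L) {
  n <- g$n
  nbr <- vector("list", n)
  bord <- vector("list", n)
  for (k in seq_along(g$b1)) {
    i <- g$b1[k]; j <- g$b2[k]
    nbr[[i]] <- c(nbr[[i]], j); nbr[[j]] <- c(nbr[[j]], i)
    bord[[i]] <- c(bord[[i]], g$bo[k]); bord[[j]] <- c(bord[[j]], g$bo[k])
  }
  z <- unname(ATOMIC_NUMBER[g$elem])
  z[is.na(z)] <- 0L
  deg <- lengths(nbr)
  bsum <- vapply(bord, sum, 0)
  inv <- (((z * 8 + deg) * 8 + bsum) * 16 + (g$charge + 4)) %% HASH_MOD
  keys <- inv
  if (radius > 0L) for (r in seq_len(radius)) {
    newinv <- numeric(n)
    for (i in seq_len(n)) {
      h <- hash_mix(r, inv[i])
      if (deg[i] > 0L) {
        nb <- nbr[[i]]; bo <- bord[[i]]
        o <- order(bo, inv[nb])
        for (k in o) h <- hash_mix(hash_mix(h, bo[k]), inv[nb[k]])
      }
      newinv[i] <- h
    }
    inv <- newinv
    keys <- c(keys, inv)
  }
  keys
}

fold_keys <- function(keys, cfg) {
  folded <- keys %% cfg$n_bits
  if (cfg$use_counts) {
    tab <- table(folded)
    bits <- as.integer(names(tab))
    o <- order(bits)
    structure(bits[o], counts = as.integer(tab)[o], n_bits = cfg$n_bits)
  } else {
    structure(sort(unique(as.integer(folded))), n_bits = cfg$n_bits)
  }
}

# ---- parsing ----------------------------------------------------------------

new_molecule_record <- function(input_smiles, canonical_smiles = NA_character_,
                                valid = FALSE, fingerprint = NULL, keys = NULL,
                                mw = NA_real_, logp = NA_real_) {
  structure(list(input_smiles = input_smiles,
                 canonical_smiles = canonical_smiles,
                 valid = valid, fingerprint = fingerprint,
                 substructure_keys = keys, mw = mw, logp = logp),
            class = "molecule_record")
}

#' @export
print.molecule_record <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("<molecule> %s  MW %.1f  logP %.2f  bits %d\n",
                x$canonical_smiles, x$mw, x$logp, length(x$fingerprint)))
  } else {
    cat(sprintf("<molecule> INVALID input %s\n", x$input_smiles))
  }
  invisible(x)
}

ob_parse_refs <- function(smiles) {
  tryCatch({
    refs <- ChemmineOB::forEachMol("SMILES", smiles, identity)
    if (length(refs) == 0L) NULL else refs
  }, error = function(e) NULL)
}

#' Parse SMILES into molecule records
#'
#' Parses each SMILES string with OpenBabel and assembles the unit consumed by
#' every metric and filter in the package: canonical SMILES, binary folded
#' circular fingerprint, unfolded substructure keys, molecular weight and
#' logP. Malformed input never raises: it yields a record with `valid = FALSE`
#' and absent descriptors, so generators emitting garbage are handled
#' uniformly.
#'
#' @param smiles Character vector of SMILES strings.
#' @param config A [fingerprint_config()].
#' @return A list of `molecule_record` objects, one per input, in order.
#'   Each record has fields `input_smiles`, `canonical_smiles`, `valid`,
#'   `fingerprint` (sorted 0-based on-bit indices with attribute `n_bits`),
#'   `substructure_keys` (unfolded circular keys, radii 0..radius), `mw`
#'   (Daltons) and `logp`.
#' @examples
#' recs <- parse_molecules(c("c1ccccc1", "not_a_molecule"))
#' vapply(recs, `[[`, logical(1), "valid")
#' @export
parse_molecules <- function(smiles, config = fingerprint_config()) {
  stopifnot(is.character(smiles), inherits(config, "fingerprint_config"))
  n <- length(smiles)
  out <- vector("list", n)
  if (n == 0L) return(out)
  # Per-molecule validity screen (a malformed line aborts whole-batch
  # conversions in OpenBabel), then batch property/molfile computation over
  # the valid subset.
  refs <- vector("list", n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    smi <- sub("\\s.*$", "", smiles[i])  # first whitespace-separated token
    if (!nzchar(smi)) { out[[i]] <- new_molecule_record(smiles[i]); next }
    r <- ob_parse_refs(smi)
    if (is.null(r)) {
      out[[i]] <- new_molecule_record(smiles[i])
    } else {
      refs[[i]] <- r[[1L]]
      ok[i] <- TRUE
    }
  }
  idx <- which(ok)
  if (length(idx) == 0L) return(out)
  props <- ChemmineOB::prop_OB(refs[idx])
  # molfile graphs are generated from the canonical SMILES, not the input,
  # so fingerprints and substructure keys are canonicalization-invariant by
  # construction (kekulization depends on the written form)
  sdftxt <- ChemmineOB::convertFormat("SMI", "SDF",
                                      paste(props$cansmi, collapse = "\n"))
  blocks <- strsplit(sdftxt, "$$$$\n", fixed = TRUE)[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  if (length(blocks) != length(idx))
    stop("internal error: molfile batch conversion returned ", length(blocks),
         " blocks for ", length(idx), " molecules")
  for (k in seq_along(idx)) {
    i <- idx[k]
    g <- parse_molfile(blocks[k])
    if (is.null(g)) { out[[i]] <- new_molecule_record(smiles[i]); next }
    keys <- circular_keys(g, config$radius)
    out[[i]] <- new_molecule_record(
      input_smiles = smiles[i],
      canonical_smiles = props$cansmi[k],
      valid = TRUE,
      fingerprint = fold_keys(keys, config),
      keys = sort(unique(keys)),
      mw = props$MW[k], logp = props$logP[k])
  }
  out
}

#' Canonicalize a single SMILES string
#'
#' @param smiles A single SMILES string.
#' @param config A [fingerprint_config()].
#' @return A `molecule_record`; `valid` is `FALSE` iff canonicalization
#'   failed, in which case fingerprint and descriptors are absent.
#' @examples
#' canonicalize("C1=CC=CC=C1")$canonical_smiles
#' @export
canonicalize <- function(smiles, config = fingerprint_config()) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  parse_molecules(smiles, config)[[1L]]
}

#' Molecular weight and logP of a parsed molecule
#'
#' @param record A valid `molecule_record`.
#' @return Named numeric vector with `mw` (Daltons) and `logp`.
#' @export
compute_descriptors <- function(record) {
  stopifnot(inherits(record, "molecule_record"))
  if (!isTRUE(record$valid))
    stop("compute_descriptors() requires a valid molecule record")
  c(mw = record$mw, logp = record$logp)
}

# ---- distance ---------------------------------------------------------------

#' Tanimoto (Jaccard) distance between two fingerprints
#'
#' `1 - |a intersect b| / |a union b|` over on-bit index sets; a true metric
#' (symmetric, triangle inequality). Two empty fingerprints are identical
#' all-zero vectors, so their distance is 0. If both fingerprints carry a
#' `counts` attribute (see [fingerprint_config()] with `use_counts = TRUE`)
#' the count form `1 - sum(min)/sum(max)` is used.
#'
#' @param a,b Integer vectors of on-bit indices (sorted, as produced by
#'   [parse_molecules()]), from the same fingerprint configuration.
#' @return Distance in \[0, 1\].
#' @examples
#' tanimoto_distance(c(1L, 2L), c(2L, 3L))  # 2/3
#' @export
tanimoto_distance <- function(a, b) {
  ca <- attr(a, "counts"); cb <- attr(b, "counts")
  if (!is.null(ca) && !is.null(cb)) {
    keys <- union(a, b)
    va <- vb <- numeric(length(keys))
    va[match(a, keys)] <- ca
    vb[match(b, keys)] <- cb
    smax <- sum(pmax(va, vb))
    if (smax == 0) return(0)
    return(1 - sum(pmin(va, vb)) / smax)
  }
  la <- length(a); lb <- length(b)
  if (la == 0L && lb == 0L) return(0)
  i <- sum(a %in% b)
  1 - i / (la + lb - i)
}

# Distances from one binary fingerprint to a list of binary fingerprints.
tanimoto_to_many <- function(fp, fps) {
  lf <- length(fp)
  vapply(fps, function(b) {
    lb <- length(b)
    if (lf == 0L && lb == 0L) return(0)
    i <- sum(fp %in% b)
    1 - i / (lf + lb - i)
  }, 0)
}
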