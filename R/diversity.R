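# Diversity measures over molecule sets: #Circles (exact branch-and-bound and
# greedy sphere exclusion), internal diversity, uniqueness, Bemis-Murcko
# scaffold counts, and MaxMin ordering.
#
# All metric operations accept an abstract distance oracle: any symmetric,
# nonnegative function of two items. Items may be fingerprints (default
# distance = Tanimoto), molecule_records (their fingerprints are used), or
# arbitrary objects paired with a custom `dist`. Circle separation uses the
# strict inequality d > D: two items exactly at the threshold conflict.

as_metric_items <- function(items) {
  if (inherits(items, "screening_library")) items <- items$records
  if (length(items) > 0L && inherits(items[[1L]], "molecule_record")) {
    valid <- vapply(items, function(r) isTRUE(r$valid), TRUE)
    if (any(!valid)) {
      warning(sum(!valid), " invalid record(s) dropped")
      items <- items[valid]
    }
    items <- lapply(items, `[[`, "fingerprint")
  }
  items
}

new_diverse_hit_result <- function(selected, threshold_D, method, n_items) {
  structure(list(count = length(selected), selected = as.integer(selected),
                 threshold_D = threshold_D, method = method,
                 n_items = as.integer(n_items)),
            class = "diverse_hit_result")
}

#' @export
print.diverse_hit_result <- function(x, ...) {
  cat(sprintf("#Circles = %d of %d items (D = %g, method = %s)\n",
              x$count, x$n_items, x$threshold_D, x$method))
  invisible(x)
}

pairwise_distance_matrix <- function(items, dist) {
  n <- length(items)
  dm <- matrix(0, n, n)
  if (n >= 2L) for (i in 1L:(n - 1L)) for (j in (i + 1L):n) {
    dm[i, j] <- dm[j, i] <- dist(items[[i]], items[[j]])
  }
  dm
}

#' Exact #Circles: maximum set of mutually distant items
#'
#' The #Circles diversity measure: the size of the largest subset whose
#' pairwise distances all exceed the threshold `D` -- equivalently, a maximum
#' independent set of the graph that connects items at distance <= D.
#' Solved by branch and bound (greedy initial bound, branching on the
#' highest-degree candidate), exact but exponential in the worst case, so a
#' size guard refuses large inputs.
#'
#' @param items List of fingerprints, `molecule_record`s, a
#'   `screening_library`, or arbitrary objects matching `dist`.
#' @param dist Distance oracle `function(x, y)`, symmetric and nonnegative.
#' @param D Distance threshold in \[0, 1\] (for Tanimoto); pairs with
#'   `d > D` may coexist, pairs with `d <= D` conflict.
#' @param max_n Size guard; inputs larger than this are refused with a
#'   pointer to [n_circles_greedy()].
#' @return A `diverse_hit_result` with fields `count`, `selected` (indices
#'   into `items`, a maximum packing), `threshold_D`, `method = "exact"`.
#' @examples
#' fps <- list(c(1L, 2L), c(2L, 3L), c(9L, 10L))
#' n_circles_exact(fps, D = 0.5)$count
#' @export
n_circles_exact <- function(items, dist = tanimoto_distance, D, max_n = 25L) {
  items <- as_metric_items(items)
  n <- length(items)
  if (n > max_n)
    stop("n_circles_exact() is exponential and limited to ", max_n,
         " items (got ", n, "); use n_circles_greedy() for large sets")
  if (n == 0L) return(new_diverse_hit_result(integer(0), D, "exact", 0L))
  dm <- pairwise_distance_matrix(items, dist)
  conflict <- dm <= D
  diag(conflict) <- FALSE

  # greedy lower bound in index order
  best <- integer(0)
  for (i in seq_len(n)) if (!any(conflict[i, best])) best <- c(best, i)
  best_env <- new.env(parent = emptyenv())
  best_env$sel <- best

  recurse <- function(sel, cand) {
    while (TRUE) {
      if (length(sel) + length(cand) <= length(best_env$sel)) return(invisible())
      if (length(cand) == 0L) {
        best_env$sel <- sel
        return(invisible())
      }
      deg <- colSums(conflict[cand, cand, drop = FALSE])
      # isolated candidates are always taken
      iso <- deg == 0L
      if (any(iso)) {
        sel <- c(sel, cand[iso])
        cand <- cand[!iso]
        next
      }
      v <- cand[which.max(deg)]
      # branch 1: include v
      recurse(c(sel, v), cand[!conflict[v, cand] & cand != v])
      # branch 2: exclude v
      cand <- setdiff(cand, v)
    }
  }
  recurse(integer(0), seq_len(n))
  new_diverse_hit_result(sort(best_env$sel), D, "exact", n)
}

#' Greedy #Circles: sphere-exclusion scan
#'
#' Scans items in the given order and keeps an item iff its distance to every
#' already-kept item exceeds `D`. The result is a maximal (not necessarily
#' maximum) packing, so its count never exceeds [n_circles_exact()] on the
#' same input. The default scan order is the input order, which makes counts
#' reproducible from a generation log.
#'
#' @inheritParams n_circles_exact
#' @param order Permutation of item indices giving the scan order.
#' @return A `diverse_hit_result` with `method = "greedy"`; `selected` is in
#'   scan order.
#' @export
n_circles_greedy <- function(items, dist = tanimoto_distance, D,
                             order = seq_along(items)) {
  items <- as_metric_items(items)
  n <- length(items)
  stopifnot(length(order) == n, all(sort(as.integer(order)) == seq_len(n)))
  selected <- integer(0)
  for (i in as.integer(order)) {
    ok <- TRUE
    for (j in selected) if (dist(items[[i]], items[[j]]) <= D) { ok <- FALSE; break }
    if (ok) selected <- c(selected, i)
  }
  new_diverse_hit_result(selected, D, "greedy", n)
}

#' Internal diversity: mean pairwise distance
#'
#' The arithmetic mean of the distance over all unordered pairs (self-pairs
#' excluded). A classical diversity measure with known pathologies: it is
#' maximized by two maximally distant items, can be inflated by a few tight
#' clusters, and can decrease when items are added.
#'
#' @inheritParams n_circles_exact
#' @return Mean pairwise distance; errors when fewer than 2 items are given.
#' @export
internal_diversity <- function(items, dist = tanimoto_distance) {
  items <- as_metric_items(items)
  n <- length(items)
  if (n < 2L) stop("internal_diversity() is undefined for fewer than 2 items")
  tot <- 0
  for (i in 1L:(n - 1L)) for (j in (i + 1L):n) tot <- tot + dist(items[[i]], items[[j]])
  tot / (n * (n - 1L) / 2)
}

drop_invalid <- function(records, what) {
  if (inherits(records, "screening_library")) records <- records$records
  valid <- vapply(records, function(r) isTRUE(r$valid), TRUE)
  if (any(!valid))
    warning(sum(!valid), " invalid record(s) skipped in ", what)
  records[valid]
}

#' Number of distinct molecules
#'
#' @param records List of `molecule_record`s; invalid records are skipped
#'   with a warning.
#' @return Number of distinct canonical SMILES.
#' @export
count_unique <- function(records) {
  records <- drop_invalid(records, "count_unique()")
  length(unique(vapply(records, `[[`, "", "canonical_smiles")))
}

#' Bemis-Murcko scaffold of a molecule
#'
#' The ring systems plus connecting linkers, obtained by iteratively deleting
#' terminal heavy atoms from the molecular graph, then re-canonicalizing.
#' Acyclic molecules reduce to the empty scaffold `""`, which is treated as a
#' single shared scaffold class.
#'
#' @param x A SMILES string or a valid `molecule_record`.
#' @return Canonical scaffold SMILES, or `""` for acyclic molecules, or `NA`
#'   for invalid input.
#' @examples
#' murcko_scaffold("Cc1ccccc1")  # benzene
#' @export
murcko_scaffold <- function(x) {
  if (inherits(x, "molecule_record")) {
    if (!isTRUE(x$valid)) return(NA_character_)
    x <- x$canonical_smiles
  }
  stopifnot(is.character(x), length(x) == 1L)
  sdftxt <- tryCatch(ChemmineOB::convertFormat("SMI", "SDF", x),
                     error = function(e) NULL)
  if (is.null(sdftxt)) return(NA_character_)
  g <- parse_molfile(sdftxt)
  if (is.null(g)) return(NA_character_)
  keep <- rep(TRUE, g$n)
  repeat {
    deg <- integer(g$n)
    for (k in seq_along(g$b1)) {
      if (keep[g$b1[k]] && keep[g$b2[k]]) {
        deg[g$b1[k]] <- deg[g$b1[k]] + 1L
        deg[g$b2[k]] <- deg[g$b2[k]] + 1L
      }
    }
    terminal <- keep & deg <= 1L
    if (!any(terminal)) break
    keep[terminal] <- FALSE
    if (!any(keep)) break
  }
  if (!any(keep)) return("")
  scaffold_smiles(g, keep)
}

# Rebuild a V2000 molfile for the kept atom subset and re-canonicalize it
# with OpenBabel (implicit hydrogens fill the cut valences).
scaffold_smiles <- function(g, keep) {
  idx <- which(keep)
  remap <- integer(g$n)
  remap[idx] <- seq_along(idx)
  ln <- g$lines
  atom_lines <- ln[4L + idx]
  bk <- which(keep[g$b1] & keep[g$b2])
  bond_lines <- sprintf("%3d%3d%3d  0", remap[g$b1[bk]], remap[g$b2[bk]], g$bo[bk])
  chg_idx <- idx[g$charge[idx] != 0L]
  chg_lines <- if (length(chg_idx) > 0L) {
    vapply(chg_idx, function(i)
      sprintf("M  CHG  1 %3d %3d", remap[i], g$charge[i]), "")
  } else character(0)
  mol <- c("", " divhits scaffold", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                   length(idx), length(bk)),
           atom_lines, bond_lines, chg_lines, "M  END", "$$$$")
  out <- tryCatch(
    ChemmineOB::convertFormat("SDF", "CAN", paste(mol, collapse = "\n")),
    error = function(e) NA_character_)
  if (is.na(out) || !nzchar(trimws(out))) return(NA_character_)
  sub("\\s.*$", "", trimws(out))
}

#' Number of distinct Bemis-Murcko scaffolds
#'
#' @inheritParams count_unique
#' @return Number of distinct scaffold classes among the valid records; all
#'   acyclic molecules share one class.
#' @export
count_scaffolds <- function(records) {
  records <- drop_invalid(records, "count_scaffolds()")
  if (length(records) == 0L) return(0L)
  smi <- unique(vapply(records, `[[`, "", "canonical_smiles"))
  sc <- vapply(smi, murcko_scaffold, "")
  length(unique(sc[!is.na(sc)]))
}

#' MaxMin diversity ordering
#'
#' Orders items so that early positions are as mutually distant as possible:
#' position 1 is `start`; each subsequent position holds the item maximizing
#' its minimum distance to all earlier positions, ties broken by smallest
#' index. This is the classical MaxMin diversity picker used to sort
#' screening libraries so that redundant molecules are evaluated last.
#'
#' @inheritParams n_circles_exact
#' @param start Index of the first item.
#' @return An integer permutation of `seq_along(items)`.
#' @export
maxmin_order <- function(items, dist = tanimoto_distance, start = 1L) {
  items <- as_metric_items(items)
  n <- length(items)
  stopifnot(n >= 1L, start >= 1L, start <= n)
  if (n == 1L) return(as.integer(start))
  ord <- integer(n)
  ord[1L] <- as.integer(start)
  binary <- is.integer(items[[1L]]) && is.null(attr(items[[1L]], "counts")) &&
    identical(dist, tanimoto_distance)
  d_to <- function(i) {
    if (binary) tanimoto_to_many(items[[i]], items) else
      vapply(items, function(x) dist(items[[i]], x), 0)
  }
  mind <- d_to(start)
  mind[start] <- -Inf
  for (k in 2L:n) {
    nxt <- which.max(mind)  # which.max takes the smallest index on ties
    ord[k] <- nxt
    if (k < n) {
      mind <- pmin(mind, d_to(nxt))
      mind[nxt] <- -Inf
    }
  }
  ord
}
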