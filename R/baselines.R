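# Virtual-screening baselines and a simple reference genetic algorithm that
# exercise the harness end-to-end. The VS baselines ignore scoring feedback;
# the mutation GA uses it, which is exactly what the run loop's caching and
# diversity-filter feedback need to be tested against.

#' Screening library
#'
#' A deduplicated collection of valid molecules used by the virtual-screening
#' baselines (the stand-in for a large public screening collection).
#'
#' @param records List of `molecule_record`s; invalid records are dropped
#'   with a warning and duplicates (by canonical SMILES) collapsed.
#' @param name Label for reports.
#' @return An object of class `screening_library` with fields `records` and
#'   `name`.
#' @export
screening_library <- function(records, name = "library") {
  valid <- vapply(records, function(r) isTRUE(r$valid), TRUE)
  if (any(!valid))
    warning(sum(!valid), " invalid record(s) dropped from screening library")
  records <- records[valid]
  can <- vapply(records, `[[`, "", "canonical_smiles")
  records <- records[!duplicated(can)]
  structure(list(records = records, name = name), class = "screening_library")
}

#' @export
print.screening_library <- function(x, ...) {
  cat(sprintf("<screening library> '%s': %d molecules\n", x$name,
              length(x$records)))
  invisible(x)
}

#' @export
length.screening_library <- function(x) length(x$records)

library_smiles <- function(library) {
  vapply(library$records, `[[`, "", "canonical_smiles")
}

#' Virtual screening in random order
#'
#' Returns a generator that proposes a uniform random permutation of the
#' library, batch by batch, never repeating a molecule; the permutation is
#' drawn from the run's seeded generator stream, so it is reproducible.
#'
#' @param library A [screening_library()].
#' @param batch_size Proposals per scoring call.
#' @return A generator function for [run_generator()].
#' @export
vs_random <- function(library, batch_size = 32L) {
  stopifnot(inherits(library, "screening_library"), length(library) >= 1L)
  smiles <- library_smiles(library)
  gen <- function(score, budget_view, seed) {
    perm <- sample.int(length(smiles))
    i <- 1L
    while (i <= length(perm)) {
      if (budget_view()$exhausted) return(invisible())
      j <- min(i + batch_size - 1L, length(perm))
      score(smiles[perm[i:j]])
      i <- j + 1L
    }
    invisible()  # library exhausted
  }
  attr(gen, "name") <- "vs-random"
  gen
}

#' Virtual screening in MaxMin order
#'
#' Returns a generator that proposes the library sorted by the MaxMin
#' diversity picker ([maxmin_order()], start fixed at index 1 for
#' reproducibility), so the molecules screened first have as large pairwise
#' distances as possible and redundant molecules are evaluated last.
#'
#' @inheritParams vs_random
#' @param start Index of the first library molecule in the ordering.
#' @return A generator function for [run_generator()].
#' @export
vs_maxmin <- function(library, batch_size = 32L, start = 1L) {
  stopifnot(inherits(library, "screening_library"), length(library) >= 1L)
  smiles <- library_smiles(library)
  fps <- lapply(library$records, `[[`, "fingerprint")
  ord <- NULL  # computed lazily, once
  gen <- function(score, budget_view, seed) {
    if (is.null(ord)) ord <<- maxmin_order(fps, start = start)
    i <- 1L
    while (i <= length(ord)) {
      if (budget_view()$exhausted) return(invisible())
      j <- min(i + batch_size - 1L, length(ord))
      score(smiles[ord[i:j]])
      i <- j + 1L
    }
    invisible()
  }
  attr(gen, "name") <- "vs-maxmin"
  gen
}

GA_ALIPHATIC <- c("C", "C", "C", "N", "O", "S", "F", "Cl", "Br")
GA_AROMATIC <- c("c", "c", "c", "n", "o", "s")
GA_CHAIN <- c("C", "C", "C", "N", "O")
GA_BRANCHES <- c("C", "CC", "CCC", "O", "OC", "N", "NC", "F", "Cl", "Br",
                 "C(F)(F)F", "C(=O)O", "C(=O)N", "[N+](=O)[O-]", "CCO",
                 "c2ccccc2")

# One random atom-level edit on a SMILES string: substitute an atom by
# another of the same aromaticity class, insert a chain atom, or delete an
# atom character. Edits are deliberately local so that offspring stay close
# to their parent in fingerprint space; anything that breaks valence or ring
# syntax is absorbed by the validity retry in the caller.
mutate_smiles_once <- function(smi) {
  ch <- strsplit(smi, "")[[1L]]
  # atom positions: letters, excluding the second character of Cl/Br and
  # bracket-atom internals
  is_atom <- grepl("[A-Za-z]", ch) & !(ch %in% c("l", "r", "H"))
  atom_pos <- which(is_atom)
  if (length(atom_pos) == 0L) return(smi)
  op <- sample(c("sub", "sub", "branch_ins", "branch_del", "ins", "del"), 1L)
  pos <- atom_pos[sample.int(length(atom_pos), 1L)]
  if (op == "branch_ins") {
    frag <- sample(GA_BRANCHES, 1L)
    return(paste0(substr(smi, 1L, pos), "(", frag, ")",
                  substring(smi, pos + 1L)))
  }
  if (op == "branch_del") {
    m <- gregexpr("\\([^()]*\\)", smi)[[1L]]
    if (m[1L] == -1L) return(smi)
    k <- sample.int(length(m), 1L)
    return(paste0(substr(smi, 1L, m[k] - 1L),
                  substring(smi, m[k] + attr(m, "match.length")[k])))
  }
  if (op == "sub") {
    aromatic <- ch[pos] %in% c("c", "n", "o", "s")
    tok <- if (aromatic) sample(GA_AROMATIC, 1L) else sample(GA_ALIPHATIC, 1L)
    # drop a trailing 'l'/'r' if we overwrite a two-character halogen
    if (pos < length(ch) && ch[pos + 1L] %in% c("l", "r") &&
        ch[pos] %in% c("C", "B"))
      ch <- ch[-(pos + 1L)]
    ch[pos] <- tok
  } else if (op == "ins") {
    ch <- append(ch, sample(GA_CHAIN, 1L), after = pos)
  } else if (length(atom_pos) > 1L) {
    if (pos < length(ch) && ch[pos + 1L] %in% c("l", "r") &&
        ch[pos] %in% c("C", "B"))
      ch <- ch[-(pos + 1L)]
    ch <- ch[-pos]
  }
  paste(ch, collapse = "")
}

#' Reference mutation genetic algorithm
#'
#' A deliberately simple feedback-using baseline (not a reproduction of any
#' published generator): keep the `population_size` best-scoring molecules
#' seen so far, mutate random parents with token-level SMILES edits, and
#' propose the offspring. Invalid offspring are retried up to `max_retries`
#' times, then the parent itself is re-proposed (the cache absorbs it). A
#' stagnation guard ends the run after `max_stagnant_batches` consecutive
#' batches that consume no budget (e.g. with `mutation_rate = 0` every
#' offspring is a cached duplicate and the run would otherwise never end).
#'
#' @param library A [screening_library()] supplying the initial population.
#' @param population_size Number of parents kept.
#' @param offspring_size Proposals per generation.
#' @param mutation_rate Expected number of edits per offspring (each edit is
#'   applied with this probability, up to 3 attempts per offspring).
#' @param max_retries Validity retries per offspring.
#' @param max_stagnant_batches Stagnation guard.
#' @return A generator function for [run_generator()].
#' @export
mutation_ga <- function(library, population_size = 24L, offspring_size = 24L,
                        mutation_rate = 1.0, max_retries = 10L,
                        max_stagnant_batches = 25L) {
  stopifnot(inherits(library, "screening_library"), length(library) >= 1L)
  seed_smiles <- library_smiles(library)
  mutate <- function(smi) {
    n_edits <- if (mutation_rate <= 0) 0L else
      max(1L, stats::rbinom(1L, 3L, min(1, mutation_rate / 3)))
    if (n_edits == 0L) return(smi)
    for (k in seq_len(max_retries)) {
      cand <- smi
      for (e in seq_len(n_edits)) cand <- mutate_smiles_once(cand)
      if (isTRUE(parse_molecules(cand)[[1L]]$valid)) return(cand)
    }
    smi  # fall back to re-proposing the parent
  }
  gen <- function(score, budget_view, seed) {
    init <- seed_smiles[sample.int(length(seed_smiles),
                                   min(population_size, length(seed_smiles)))]
    sc <- score(init)
    pop <- data.frame(smiles = init, score = sc, stringsAsFactors = FALSE)
    stagnant <- 0L
    repeat {
      bv <- budget_view()
      if (bv$exhausted || stagnant >= max_stagnant_batches) return(invisible())
      # rank-weighted parent selection: strong scorers reproduce more often
      w <- 0.85^(seq_len(nrow(pop)) - 1L)
      parents <- pop$smiles[sample.int(nrow(pop), offspring_size,
                                       replace = TRUE, prob = w)]
      offspring <- vapply(parents, mutate, "", USE.NAMES = FALSE)
      before <- budget_view()$calls_used
      sc <- score(offspring)
      stagnant <- if (budget_view()$calls_used > before) 0L else stagnant + 1L
      pool <- rbind(pop, data.frame(smiles = offspring, score = sc,
                                    stringsAsFactors = FALSE))
      pool <- pool[!duplicated(pool$smiles), ]
      pool <- pool[order(-pool$score), ]
      pop <- utils::head(pool, population_size)
    }
  }
  attr(gen, "name") <- "mutation-ga"
  gen
}
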