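#' Reproduction parameters
#'
#' @param mode `"sexual"` (pairing, recombination, assortment) or
#'   `"asexual"` (clonal copy of both haplotypes; recombination and
#'   assortment are bypassed).
#' @param maturity_age First age class (0-based) at which reproduction is
#'   possible.
#' @param menopause_age Optional age class from which reproduction is
#'   impossible; must exceed `maturity_age`.
#' @param oviparous Logical; if `TRUE` offspring enter as eggs, invulnerable
#'   to all mortality, and hatch per `hatching_policy`.
#' @param incubation Incubation time in steps (`fixed_incubation` policy).
#'   Eggs laid at step `s` hatch at the end of step `s + incubation`, i.e.,
#'   with `incubation = 0` they are alive the step after laying.
#' @param hatching_policy `"fixed_incubation"` or `"when_adults_extinct"`
#'   (all eggs hatch at the first step with zero living non-egg individuals;
#'   non-overlapping generations).
#' @param recombination_rate Expected crossovers per haplotype pair.
#' @param egg_selection Which laid eggs are carried into the next generation
#'   under `when_adults_extinct`: `"all"`, `"earliest"` (laid-step ascending)
#'   or `"latest"` (laid-step descending), truncated at `egg_cap` eggs.
#' @param egg_cap Maximum eggs carried over (default unlimited).
#' @return An object of class `reproduction_params`.
#' @export
reproduction_params <- function(mode = "sexual", maturity_age = 10L,
                                menopause_age = NULL, oviparous = FALSE,
                                incubation = 0L,
                                hatching_policy = "fixed_incubation",
                                recombination_rate = 1,
                                egg_selection = "all", egg_cap = Inf) {
  mode <- match.arg(mode, c("sexual", "asexual"))
  hatching_policy <- match.arg(hatching_policy,
                               c("fixed_incubation", "when_adults_extinct"))
  egg_selection <- match.arg(egg_selection, c("all", "earliest", "latest"))
  maturity_age <- as.integer(maturity_age)
  if (maturity_age < 0L) stop("maturity_age must be >= 0", call. = FALSE)
  if (!is.null(menopause_age)) {
    menopause_age <- as.integer(menopause_age)
    if (menopause_age <= maturity_age) {
      stop("menopause_age must exceed maturity_age", call. = FALSE)
    }
  }
  if (incubation < 0L) stop("incubation must be >= 0", call. = FALSE)
  if (recombination_rate < 0) {
    stop("recombination_rate must be >= 0", call. = FALSE)
  }
  structure(list(mode = mode, maturity_age = maturity_age,
                 menopause_age = menopause_age, oviparous = oviparous,
                 incubation = as.integer(incubation),
                 hatching_policy = hatching_policy,
                 recombination_rate = recombination_rate,
                 egg_selection = egg_selection, egg_cap = egg_cap),
            class = "reproduction_params")
}

#' Reproductive eligibility and attempts
#'
#' An individual is eligible iff it is alive, not an egg, and its age is in
#' `[maturity_age, menopause_age)`. Each eligible individual then attempts
#' reproduction with probability equal to its fertility phenotype at its
#' current age.
#'
#' @param ages Integer ages of the living, non-egg individuals.
#' @param fertility Per-individual fertility probability at each
#'   individual's current age.
#' @param params A [reproduction_params()].
#' @return A list with logical masks `eligible` and `attempting`.
#' @export
eligible_parents <- function(ages, fertility, params) {
  eligible <- ages >= params$maturity_age
  if (!is.null(params$menopause_age)) {
    eligible <- eligible & ages < params$menopause_age
  }
  attempting <- eligible & stats::runif(length(ages)) < fertility
  list(eligible = eligible, attempting = attempting)
}

#' Pair mates uniformly at random
#'
#' A uniformly random permutation of the attempting individuals is split
#' into consecutive disjoint pairs; each individual mates at most once per
#' step, and an odd leftover individual does not reproduce. Pairing ignores
#' age and genotype (random mating).
#'
#' @param ids Vector of attempting individual ids.
#' @return A list with `pairs` (a `k x 2` matrix of ids) and `unmated`
#'   (leftover ids).
#' @export
pair_mates <- function(ids) {
  n <- length(ids)
  if (n < 2L) {
    return(list(pairs = matrix(ids[0], ncol = 2L), unmated = ids))
  }
  perm <- ids[sample.int(n)]
  k <- n %/% 2L
  pairs <- matrix(perm[seq_len(2L * k)], ncol = 2L, byrow = TRUE)
  list(pairs = pairs,
       unmated = if (n %% 2L) perm[n] else ids[0])
}

#' Generate offspring genomes
#'
#' Sexual mode: each pair produces exactly one offspring by recombining each
#' parent's haplotypes, assorting one recombined haplotype from each parent,
#' and mutating with the offspring-relevant germline rate (the rate of the
#' first-listed pair member, the mother of record). Asexual mode: each
#' attempting parent clones both haplotypes (recombination and assortment
#' bypassed), then mutates.
#'
#' @param genomes A `genome_pool` holding the parents.
#' @param parents_a Column indices of the first parents (mothers of record),
#'   or of the sole parents in asexual mode.
#' @param parents_b Column indices of the second parents (sexual mode), or
#'   `NULL`.
#' @param mutation_rate Per-bit germline mutation rate per offspring
#'   (recycled).
#' @param recombination_rate Expected crossovers per parent per meiosis.
#' @param asymmetry Mutation asymmetry ratio (see [mutate_genomes()]).
#' @return A `genome_pool` of `length(parents_a)` offspring.
#' @export
generate_offspring <- function(genomes, parents_a, parents_b = NULL,
                               mutation_rate = 0, recombination_rate = 0,
                               asymmetry = 1) {
  L <- n_loci(genomes)
  kids <- offspring_core(genomes, L, parents_a, parents_b,
                         recombination_rate)
  kids <- mutate_core(kids, rep_len(mutation_rate,
                                    max(ncol(kids), 1L))[seq_len(ncol(kids))],
                      asymmetry = asymmetry)
  new_genome_pool(kids, L)
}

# Offspring genome assembly on a plain bit matrix. Sexual: recombine each
# parent's haplotype pair, then assort one recombined haplotype from each.
# Asexual: copy both haplotypes unchanged (pre-mutation).
offspring_core <- function(mat, L, parents_a, parents_b, recombination_rate) {
  k <- length(parents_a)
  kids <- matrix(0L, nrow = 2L * L, ncol = k)
  if (is.null(parents_b)) {
    if (k) kids[] <- mat[, parents_a]
  } else {
    stopifnot(length(parents_b) == k)
    lo <- seq_len(L)
    for (j in seq_len(k)) {
      ga <- recombine_col(mat[, parents_a[j]], L, recombination_rate)
      gb <- recombine_col(mat[, parents_b[j]], L, recombination_rate)
      offa <- if (sample.int(2L, 1L) == 1L) 0L else L
      offb <- if (sample.int(2L, 1L) == 1L) 0L else L
      kids[lo, j] <- ga[offa + lo]
      kids[L + lo, j] <- gb[offb + lo]
    }
  }
  kids
}

# Rank egg indices for carry-over into the next generation.
select_eggs <- function(laid_step, policy, cap) {
  ord <- switch(policy,
    all = seq_along(laid_step),
    earliest = order(laid_step, seq_along(laid_step)),
    latest = order(-laid_step, seq_along(laid_step))
  )
  ord[seq_len(min(length(ord), cap))]
}
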