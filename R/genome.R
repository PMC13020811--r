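#' @keywords internal
new_genome_pool <- function(mat, n_loci) {
  stopifnot(is.matrix(mat), nrow(mat) == 2L * n_loci)
  structure(mat, n_loci = as.integer(n_loci), class = "genome_pool")
}

#' Number of individuals / loci in a genome pool
#' @param pool A `genome_pool`.
#' @return Integer count.
#' @export
n_individuals <- function(pool) ncol(pool)

#' @rdname n_individuals
#' @export
n_loci <- function(pool) attr(pool, "n_loci")

#' @export
print.genome_pool <- function(x, ...) {
  cat("<genome_pool> ", ncol(x), " individuals x 2 haplotypes x ",
      n_loci(x), " bits\n", sep = "")
  invisible(x)
}

#' Initialize a pool of bit-string genomes
#'
#' Each individual carries two haplotypes of `total_bits` bits (both in
#' sexual and asexual populations; asexual inheritance copies both). Every
#' bit belonging to a trait's blocks is set to 1 independently with that
#' trait's `ones_fraction`; identical fractions across age classes give an
#' age-flat (non-aging) expected phenotype.
#'
#' @param n Number of individuals (>= 1).
#' @param arch A [build_architecture()] result.
#' @param ones_fraction A single fraction in `[0, 1]`, or a named vector/list
#'   mapping trait names to fractions. Traits not named fall back to the
#'   fraction implied by the trait's `initial` value
#'   (`(initial - lower) / (upper - lower)`).
#' @return A `genome_pool`: an integer matrix with one column per individual
#'   and `2 * total_bits` rows (haplotype 1 then haplotype 2).
#' @examples
#' arch <- build_architecture(list(trait_spec("survival", TRUE, 4)), 10)
#' g <- init_genomes(5, arch, ones_fraction = 1)
#' all(g == 1L)
#' @export
init_genomes <- function(n, arch, ones_fraction = NULL) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  L <- arch$total_bits
  mat <- matrix(0L, nrow = 2L * L, ncol = n)
  for (tr in arch$traits) {
    if (!tr$evolvable) next
    f <- trait_ones_fraction(tr, ones_fraction)
    if (is.na(f) || f < 0 || f > 1) {
      stop("ones_fraction for trait '", tr$name, "' must be in [0, 1]",
           call. = FALSE)
    }
    rows <- trait_bit_rows(arch, tr$name)
    rows2 <- c(rows, L + rows)
    mat[rows2, ] <- matrix(
      as.integer(stats::runif(length(rows2) * n) < f),
      nrow = length(rows2)
    )
  }
  new_genome_pool(mat, L)
}

trait_ones_fraction <- function(tr, ones_fraction) {
  f <- NULL
  if (!is.null(ones_fraction)) {
    if (is.null(names(ones_fraction)) && length(ones_fraction) == 1L) {
      f <- as.numeric(ones_fraction)
    } else if (tr$name %in% names(ones_fraction)) {
      f <- as.numeric(ones_fraction[[tr$name]])
    }
  }
  if (is.null(f)) {
    f <- if (tr$upper > tr$lower) {
      (tr$initial - tr$lower) / (tr$upper - tr$lower)
    } else 1
  }
  f
}

#' Interpret genomes into age-specific phenotypes
#'
#' The genotype-to-phenotype map: for each individual, trait and age-class
#' block, the raw score is the fraction of bits (over both haplotypes and all
#' bits of the block) whose value matches the drift map's beneficial
#' direction; the trait value is `lower + raw * (upper - lower)`.
#' Non-evolvable traits are filled with their configured constants.
#' Reproduction is forced to 0 for age classes below `maturity` and at or
#' above `menopause`.
#'
#' @param genomes A `genome_pool`.
#' @param arch The matching `genome_architecture`.
#' @param drift Optional drift map (integer vector of length `total_bits`);
#'   defaults to all-ones ([default_drift_map()]).
#' @param maturity Age class of sexual maturity (0-based).
#' @param menopause Optional age class at menopause; reproduction is 0 from
#'   this age on.
#' @return An object of class `phenotype_table`: a list with one element per
#'   trait. Age-dependent traits are `n_age_classes x n` matrices (rows are
#'   age classes 0-based); age-independent traits are length-`n` vectors.
#' @export
interpret_phenotypes <- function(genomes, arch, drift = NULL,
                                 maturity = 0L, menopause = NULL) {
  L <- arch$total_bits
  if (nrow(genomes) != 2L * L) {
    stop("genome bit count does not match architecture", call. = FALSE)
  }
  if (is.null(drift)) drift <- default_drift_map(arch)
  stopifnot(length(drift) == L)
  n <- ncol(genomes)

  out <- list()
  for (tr in arch$traits) {
    n_rows_out <- if (tr$age_dependent) arch$n_age_classes else 1L
    if (!tr$evolvable) {
      val <- if (tr$age_dependent) {
        matrix(tr$initial, n_rows_out, n)
      } else rep.int(tr$initial, n)
    } else {
      rows <- trait_bit_rows(arch, tr$name)
      target <- drift[rows]
      matches <- (genomes[rows, , drop = FALSE] == target) +
                 (genomes[L + rows, , drop = FALSE] == target)
      raw <- rowsum(matches, trait_block_ids(arch, tr$name),
                    reorder = TRUE) / (2 * tr$bits_per_block)
      val <- tr$lower + raw * (tr$upper - tr$lower)
      if (!tr$age_dependent) val <- as.numeric(val[1L, ])
    }
    out[[tr$name]] <- val
  }

  if (!is.null(out$reproduction) && is.matrix(out$reproduction)) {
    maturity <- as.integer(maturity)
    if (maturity > 0L) out$reproduction[seq_len(min(maturity, nrow(out$reproduction))), ] <- 0
    if (!is.null(menopause)) {
      men <- as.integer(menopause)
      if (men < nrow(out$reproduction)) {
        out$reproduction[(men + 1L):nrow(out$reproduction), ] <- 0
      }
    }
  }
  structure(out, n_age_classes = arch$n_age_classes,
            class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  n <- if (is.matrix(x[[1]])) ncol(x[[1]]) else length(x[[1]])
  cat("<phenotype_table> ", n, " individuals; traits: ",
      paste(names(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy a phenotype table into a long tibble
#'
#' @param x A `phenotype_table`.
#' @param ... Unused.
#' @return A tibble with columns `individual` (1-based), `trait`,
#'   `age_class` (0-based; `NA` for age-independent traits) and `value`.
#' @export
tidy.phenotype_table <- function(x, ...) {
  purrr::imap_dfr(unclass(x), function(val, trait) {
    if (is.matrix(val)) {
      tibble::tibble(
        individual = rep(seq_len(ncol(val)), each = nrow(val)),
        trait = trait,
        age_class = rep.int(0:(nrow(val) - 1L), ncol(val)),
        value = as.numeric(val)
      )
    } else {
      tibble::tibble(individual = seq_along(val), trait = trait,
                     age_class = NA_integer_, value = as.numeric(val))
    }
  })
}

#' Mutate genomes (germline)
#'
#' Each bit flips independently with its individual's per-bit rate. Flips are
#' symmetric (0 to 1 and 1 to 0 equally likely) unless `asymmetry` differs
#' from 1. Mutation acts only on offspring genomes at birth; genomes are
#' stable across life (no somatic mutation).
#'
#' @param genomes A `genome_pool`.
#' @param rate Per-bit mutation probability: a scalar or one value per
#'   individual.
#' @param asymmetry Ratio of the 0-to-1 rate to the 1-to-0 rate. The mean of
#'   the two directional rates is kept equal to `rate`.
#' @return The mutated `genome_pool`.
#' @export
mutate_genomes <- function(genomes, rate, asymmetry = 1) {
  mat <- mutate_core(genomes, rate, asymmetry)
  attributes(mat) <- attributes(genomes)
  mat
}

# Mutation core on a plain bit matrix (columns = individuals). The
# symmetric path draws the flip count per individual from a binomial and
# places flips uniformly without replacement, which is exactly the per-bit
# independent Bernoulli process.
mutate_core <- function(mat, rate, asymmetry = 1) {
  n <- ncol(mat)
  m <- nrow(mat)
  rate <- rep_len(as.numeric(rate), max(n, 1L))[seq_len(n)]
  if (any(rate < 0 | rate > 1)) {
    stop("mutation rate must be in [0, 1]", call. = FALSE)
  }
  if (asymmetry <= 0) stop("asymmetry must be > 0", call. = FALSE)
  if (n == 0L || all(rate == 0)) return(mat)
  p01 <- rate * 2 * asymmetry / (1 + asymmetry)
  p10 <- rate * 2 / (1 + asymmetry)
  if (any(p01 > 1 | p10 > 1)) {
    stop("rate/asymmetry combination implies a directional rate > 1",
         call. = FALSE)
  }
  if (asymmetry == 1) {
    nf <- stats::rbinom(n, m, rate)
    for (i in which(nf > 0L)) {
      pos <- sample.int(m, nf[i])
      mat[pos, i] <- 1L - mat[pos, i]
    }
  } else {
    for (i in seq_len(n)) {
      if (rate[i] == 0) next
      zeros <- which(mat[, i] == 0L)
      ones <- which(mat[, i] == 1L)
      up <- zeros[stats::runif(length(zeros)) < p01[i]]
      down <- ones[stats::runif(length(ones)) < p10[i]]
      mat[up, i] <- 1L
      mat[down, i] <- 0L
    }
  }
  mat
}

# Core crossover on a length-2L genome column (hap1 = 1:L, hap2 = L+1:2L).
# Crossover count ~ Poisson(rate); cut points uniform without replacement
# among the L-1 inter-locus boundaries; segments alternate haplotypes, the
# first segment unchanged. The unordered bit pair at each locus is conserved.
recombine_col <- function(g, L, rate) {
  n_cross <- stats::rpois(1L, rate)
  if (n_cross == 0L || L < 2L) return(g)
  n_cross <- min(n_cross, L - 1L)
  cuts <- sample.int(L - 1L, n_cross)
  swap <- (cumsum(tabulate(cuts, L - 1L)) %% 2L) == 1L
  idx <- which(c(FALSE, swap))
  if (length(idx)) {
    tmp <- g[idx]
    g[idx] <- g[L + idx]
    g[L + idx] <- tmp
  }
  g
}

#' Recombine a pair of haplotypes
#'
#' The number of crossovers is drawn from a Poisson law with mean `rate`;
#' crossover points are uniform without replacement among inter-locus
#' boundaries, and segments between successive crossovers alternate between
#' the two haplotypes (the segment before the first crossover is unchanged).
#' The unordered pair of bits at each locus is conserved.
#'
#' @param haplotypes A `2 x L` integer matrix (one row per haplotype).
#' @param rate Expected number of crossovers (>= 0).
#' @return A `2 x L` matrix of recombined haplotypes.
#' @export
recombine <- function(haplotypes, rate) {
  stopifnot(is.matrix(haplotypes), nrow(haplotypes) == 2L)
  if (rate < 0) stop("recombination rate must be >= 0", call. = FALSE)
  L <- ncol(haplotypes)
  g <- recombine_col(c(haplotypes[1L, ], haplotypes[2L, ]), L, rate)
  rbind(g[seq_len(L)], g[L + seq_len(L)])
}

#' Assort parental haplotypes into an offspring genome
#'
#' The offspring's first haplotype is one of parent A's two (recombined)
#' haplotypes chosen uniformly at random, and its second haplotype likewise
#' one of parent B's.
#'
#' @param parent_a,parent_b `2 x L` haplotype matrices (recombined).
#' @return A `2 x L` offspring haplotype matrix.
#' @export
assort <- function(parent_a, parent_b) {
  stopifnot(is.matrix(parent_a), is.matrix(parent_b),
            nrow(parent_a) == 2L, nrow(parent_b) == 2L,
            ncol(parent_a) == ncol(parent_b))
  rbind(parent_a[sample.int(2L, 1L), ], parent_b[sample.int(2L, 1L), ])
}

#' Extract the haplotype matrix from a genome pool
#'
#' @param pool A `genome_pool`.
#' @return An integer matrix with `2 * n` rows (haplotypes; the two
#'   haplotypes of individual `i` are rows `2i - 1` and `2i`) and `total_bits`
#'   columns (0-based locus order of the architecture layout).
#' @export
genome_haplotypes <- function(pool) {
  L <- n_loci(pool)
  n <- ncol(pool)
  if (n == 0L) return(matrix(0L, nrow = 0L, ncol = L))
  out <- matrix(0L, nrow = 2L * n, ncol = L)
  out[seq(1L, 2L * n, by = 2L), ] <- t(pool[seq_len(L), , drop = FALSE])
  out[seq(2L, 2L * n, by = 2L), ] <- t(pool[L + seq_len(L), , drop = FALSE])
  out
}
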