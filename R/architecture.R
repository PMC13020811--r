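#' Define a heritable life-history trait
#'
#' A trait specification describes how one life-history trait (age-specific
#' survival probability, reproduction probability, or germline mutation rate)
#' is encoded on the bit-string genome. Evolvable traits are allocated one
#' block of `bits_per_block` bits per age class (age-dependent traits) or a
#' single block (age-independent traits); the fraction of bits in a block that
#' match the environment's beneficial direction is mapped linearly onto
#' `[lower, upper]`. Non-evolvable traits are constants taken from the
#' configuration and receive no bits.
#'
#' @param name One of `"survival"`, `"reproduction"`, `"mutation_rate"`.
#' @param age_dependent Logical; does the trait take a separate value per age
#'   class?
#' @param bits_per_block Number of bits per block (per age class for
#'   age-dependent traits). The per-bit effect size on the trait value is
#'   `(upper - lower) / (2 * bits_per_block)` (two haplotypes).
#' @param lower,upper Trait value bounds, probabilities per simulation step.
#' @param evolvable Logical; if `FALSE` the trait is the constant `initial`
#'   and no bits are allocated.
#' @param initial Initial/constant trait value. For evolvable traits this is
#'   only used to derive a default initialization fraction; for non-evolvable
#'   traits it is the trait value.
#' @return An object of class `trait_spec`.
#' @examples
#' trait_spec("survival", age_dependent = TRUE, bits_per_block = 8)
#' @export
trait_spec <- function(name,
                       age_dependent = TRUE,
                       bits_per_block = 8L,
                       lower = 0,
                       upper = if (name == "reproduction") 0.5 else 1,
                       evolvable = TRUE,
                       initial = upper) {
  name <- match.arg(name, c("survival", "reproduction", "mutation_rate"))
  if (!is.numeric(lower) || !is.numeric(upper) || lower < 0 || upper > 1 ||
      lower > upper) {
    stop("trait '", name, "': bounds must satisfy 0 <= lower <= upper <= 1",
         call. = FALSE)
  }
  bits_per_block <- as.integer(bits_per_block)
  if (evolvable && bits_per_block < 1L) {
    stop("trait '", name, "': bits_per_block must be >= 1", call. = FALSE)
  }
  if (initial < lower - 1e-12 || initial > upper + 1e-12) {
    stop("trait '", name, "': initial value outside [lower, upper]",
         call. = FALSE)
  }
  structure(
    list(name = name, age_dependent = isTRUE(age_dependent),
         bits_per_block = bits_per_block, lower = lower, upper = upper,
         evolvable = isTRUE(evolvable), initial = initial),
    class = "trait_spec"
  )
}

#' Build the genome architecture
#'
#' Lays out the bit-string genome: every evolvable trait gets one block of
#' bits per age class (or a single block if age-independent), and every bit
#' position maps to exactly one (trait, age class, offset) triple. The layout
#' is the genotype-to-phenotype contract used by [interpret_phenotypes()],
#' [compute_sfs()] annotation and the genotype dump sidecar.
#'
#' @param traits A list of [trait_spec()] objects, or a `sim_config` whose
#'   trait block is used.
#' @param n_age_classes Number of discrete age classes (simulation-step
#'   units). Ignored when `traits` is a `sim_config`.
#' @return An object of class `genome_architecture` with elements
#'   `n_age_classes`, `traits` (named list), `total_bits` (per haplotype) and
#'   `layout`, a tibble with one row per bit: `bit` (0-based position),
#'   `trait`, `age_class` (0-based; `NA` for age-independent traits),
#'   `offset` (bit within block) and `effect_size` (change in trait value per
#'   matching bit over both haplotypes).
#' @examples
#' arch <- build_architecture(list(
#'   trait_spec("survival", TRUE, 8),
#'   trait_spec("reproduction", TRUE, 8)
#' ), n_age_classes = 50)
#' arch$total_bits # 800
#' @export
build_architecture <- function(traits, n_age_classes = 50L) {
  if (inherits(traits, "sim_config")) {
    n_age_classes <- traits$n_age_classes
    traits <- traits$traits
  }
  n_age_classes <- as.integer(n_age_classes)
  if (is.na(n_age_classes) || n_age_classes < 1L) {
    stop("n_age_classes must be >= 1", call. = FALSE)
  }
  if (inherits(traits, "trait_spec")) traits <- list(traits)
  stopifnot(length(traits) >= 1L)
  names(traits) <- vapply(traits, function(t) t$name, character(1))
  if (anyDuplicated(names(traits))) {
    stop("duplicate trait names in architecture", call. = FALSE)
  }

  rows <- list()
  cursor <- 0L
  for (tr in traits) {
    if (!tr$evolvable) next
    n_blocks <- if (tr$age_dependent) n_age_classes else 1L
    b <- tr$bits_per_block
    n <- n_blocks * b
    rows[[tr$name]] <- tibble::tibble(
      bit = cursor + seq_len(n) - 1L,
      trait = tr$name,
      age_class = if (tr$age_dependent) rep(0:(n_blocks - 1L), each = b)
                  else NA_integer_,
      offset = rep.int(0:(b - 1L), n_blocks),
      effect_size = (tr$upper - tr$lower) / (2 * b)
    )
    cursor <- cursor + n
  }
  layout <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(bit = integer(), trait = character(),
                   age_class = integer(), offset = integer(),
                   effect_size = numeric())

  structure(
    list(n_age_classes = n_age_classes, traits = traits,
         total_bits = cursor, layout = layout),
    class = "genome_architecture"
  )
}

#' @export
print.genome_architecture <- function(x, ...) {
  cat("<genome_architecture> ", x$total_bits, " bits/haplotype, ",
      x$n_age_classes, " age classes\n", sep = "")
  for (tr in x$traits) {
    cat(sprintf("  %-13s %s, %s, bounds [%g, %g]%s\n", tr$name,
                if (tr$age_dependent) "age-dependent" else "age-independent",
                if (tr$evolvable)
                  paste0(tr$bits_per_block, " bits/block")
                else paste0("constant ", tr$initial),
                tr$lower, tr$upper,
                if (tr$evolvable) "" else " (no bits)"))
  }
  invisible(x)
}

# Row indices (1-based, within one haplotype) of a trait's bits.
trait_bit_rows <- function(arch, trait) {
  which(arch$layout$trait == trait)
}

# Block id (1-based) per bit for a trait; age-independent traits have one
# block. Used to pool bit counts per age class with rowsum().
trait_block_ids <- function(arch, trait) {
  lay <- arch$layout[arch$layout$trait == trait, ]
  if (all(is.na(lay$age_class))) rep(1L, nrow(lay)) else lay$age_class + 1L
}

#' Default drift map (all loci beneficial as 1)
#'
#' The drift map stores, per locus, which bit value is currently beneficial.
#' When environmental drift is disabled the map stays all-ones.
#'
#' @param arch A `genome_architecture`.
#' @return Integer vector of length `total_bits`, all 1.
#' @export
default_drift_map <- function(arch) {
  rep.int(1L, arch$total_bits)
}
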