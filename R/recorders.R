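#' Observed life-history curves from the demographic ledgers
#'
#' Period life table over a set of recording windows: the exposure at age
#' `a` is the number of individuals that entered age class `a` during the
#' windows; observed mortality `q(a)` divides all-cause deaths at age `a` by
#' that exposure; survivorship is `l(a) = prod_{x<a}(1 - q(x))` with
#' `l(0) = 1`; fertility divides births to parents aged `a` by the exposure.
#' Ages with zero exposure have undefined (`NA`) rates, not zero. Eggs are
#' not part of any denominator.
#'
#' @param run A `sim_run`.
#' @param windows Window indices to aggregate (default: all).
#' @return A `life_history_curves` tibble with columns `age_class`
#'   (0 .. n_age_classes; the terminal row only carries survivorship),
#'   `mortality`, `survivorship` (at entry to the age class), `fertility`
#'   and `flavor = "observed"`.
#' @export
life_table_observed <- function(run, windows = NULL) {
  stopifnot(inherits(run, "sim_run"))
  d <- run$ledgers$deaths
  b <- run$ledgers$births
  dem <- run$ledgers$demography
  if (!is.null(windows)) {
    d <- d[d$window %in% windows, ]
    b <- b[b$window %in% windows, ]
    dem <- dem[dem$window %in% windows, ]
  }
  if (!nrow(dem) || sum(dem$entering[dem$age_class == 0]) == 0) {
    stop("selected windows have no exposure at age 0", call. = FALSE)
  }
  n_age <- run$architecture$n_age_classes
  deaths <- stats::aggregate(deaths ~ age_class, data = d, FUN = sum)$deaths
  births <- stats::aggregate(births ~ age_class, data = b, FUN = sum)$births
  exposure <- stats::aggregate(entering ~ age_class, data = dem,
                               FUN = sum)$entering
  q <- ifelse(exposure > 0, deaths / exposure, NA_real_)
  q <- pmin(q, 1)
  f <- ifelse(exposure > 0, births / exposure, NA_real_)
  l <- cumprod(c(1, 1 - q))
  new_life_history_curves(
    age_class = 0:n_age,
    mortality = c(q, NA_real_),
    survivorship = l,
    fertility = c(f, NA_real_),
    flavor = "observed",
    exposure = c(exposure, NA_real_)
  )
}

new_life_history_curves <- function(age_class, mortality, survivorship,
                                    fertility, flavor, exposure = NULL) {
  out <- tibble::tibble(age_class = age_class, mortality = mortality,
                        survivorship = survivorship, fertility = fertility,
                        flavor = flavor)
  if (!is.null(exposure)) out$exposure <- exposure
  class(out) <- c("life_history_curves", class(out))
  out
}

#' Intrinsic life-history curves from phenotypes
#'
#' Population-mean intrinsic mortality at age `a` is the mean over living
#' individuals of `1 - survival(a)`; intrinsic survivorship is the
#' cumulative product of `(1 - mortality)` -- the survivorship a cohort
#' would display if intrinsic mortality were the only death source.
#' Per-individual curves are available through [tidy.phenotype_table()].
#'
#' @param x A `sim_run` (its final phenotype snapshot is used), one element
#'   of a run's `phenotypes` list, or a `phenotype_table`.
#' @return A `life_history_curves` tibble with `flavor = "intrinsic"`, laid
#'   out as in [life_table_observed()].
#' @export
intrinsic_curves <- function(x) {
  if (inherits(x, "sim_run")) {
    x <- x$phenotypes[[length(x$phenotypes)]]
  }
  surv <- x$survival
  fert <- x$reproduction
  if (is.null(surv) || ncol(surv) == 0) {
    stop("no phenotypes available (population empty)", call. = FALSE)
  }
  mu <- 1 - rowMeans(surv)
  fbar <- rowMeans(fert)
  l <- cumprod(c(1, 1 - mu))
  new_life_history_curves(
    age_class = 0:length(mu),
    mortality = c(mu, NA_real_),
    survivorship = l,
    fertility = c(fbar, NA_real_),
    flavor = "intrinsic"
  )
}

#' Site frequency spectrum with effect annotation
#'
#' Per-locus allele frequency is the fraction of haplotypes carrying a 1;
#' the binned spectrum covers polymorphic loci only (fixed loci at
#' frequency 0 or 1 are excluded unless `include_fixed`). Each locus is
#' annotated from the architecture layout and the current drift map: the
#' trait and age class it affects, and the signed effect of carrying a 1
#' (positive when 1 is the beneficial allele under the drift map).
#'
#' @param x A `sim_run` (its final genotype dump is used), a `genome_pool`,
#'   or a haplotype matrix as returned by [genome_haplotypes()].
#' @param arch The `genome_architecture` (taken from the run if omitted).
#' @param drift Drift map (taken from the run/defaults if omitted).
#' @param bins Number of equal-width frequency bins.
#' @param include_fixed Logical; include fixed loci in the binned spectrum.
#' @return An `sfs_result`: list with `loci` (tibble: `bit`, `trait`,
#'   `age_class`, `effect`, `frequency`) and `spectrum` (tibble: `bin`,
#'   `lower`, `upper`, `count`).
#' @export
compute_sfs <- function(x, arch = NULL, drift = NULL, bins = 10L,
                        include_fixed = FALSE) {
  if (inherits(x, "sim_run")) {
    snap <- x$genotypes[[length(x$genotypes)]]
    haps <- snap$haplotypes
    if (is.null(drift)) drift <- snap$drift
    if (is.null(arch)) arch <- x$architecture
  } else if (inherits(x, "genome_pool")) {
    haps <- genome_haplotypes(x)
  } else {
    haps <- x
  }
  if (is.null(haps) || nrow(haps) < 2L) {
    stop("at least 2 haplotypes are required", call. = FALSE)
  }
  if (is.null(arch)) stop("architecture required", call. = FALSE)
  if (is.null(drift)) drift <- default_drift_map(arch)
  freq <- colMeans(haps)
  loci <- dplyr::mutate(
    arch$layout[, c("bit", "trait", "age_class", "effect_size")],
    effect = ifelse(drift == 1L, .data$effect_size, -.data$effect_size),
    frequency = freq
  )
  loci$effect_size <- NULL
  poly <- if (include_fixed) loci else
    loci[loci$frequency > 0 & loci$frequency < 1, ]
  breaks <- seq(0, 1, length.out = bins + 1L)
  bin <- cut(poly$frequency, breaks = breaks, include.lowest = TRUE,
             labels = FALSE)
  counts <- tabulate(bin, bins)
  structure(
    list(loci = loci,
         spectrum = tibble::tibble(bin = seq_len(bins),
                                   lower = breaks[-length(breaks)],
                                   upper = breaks[-1L],
                                   count = counts)),
    class = "sfs_result"
  )
}

#' @export
print.sfs_result <- function(x, ...) {
  n_poly <- sum(x$spectrum$count)
  cat("<sfs_result> ", nrow(x$loci), " loci, ", n_poly,
      " in binned spectrum\n", sep = "")
  print(x$spectrum)
  invisible(x)
}

#' Summary life-history metrics
#'
#' Median lifespan is the median age at death; life expectancy at birth is
#' the sum of the survivorship values over all age classes (`l(0) = 1`
#' included; one age class is one simulation step); maximum lifespan is the
#' highest observed age at death. From a `life_history_curves` object the
#' median is the linearly interpolated age at which survivorship crosses
#' 0.5 (for intrinsic curves this is the median intrinsic lifespan).
#'
#' @param x A `sim_run` (deaths ledger) or a `life_history_curves` tibble.
#' @param windows Window indices to aggregate (runs only; default all).
#' @return A one-row tibble: `median_lifespan`, `life_expectancy`,
#'   `max_lifespan`, `n_deaths` (`NA` where undefined, e.g. no deaths).
#' @export
summary_metrics <- function(x, windows = NULL) {
  if (inherits(x, "life_history_curves")) {
    l <- x$survivorship
    return(tibble::tibble(
      median_lifespan = survivorship_median(0:(length(l) - 1L), l),
      life_expectancy = sum(l, na.rm = TRUE),
      max_lifespan = NA_real_,
      n_deaths = NA_real_
    ))
  }
  stopifnot(inherits(x, "sim_run"))
  d <- x$ledgers$deaths
  if (!is.null(windows)) d <- d[d$window %in% windows, ]
  counts <- stats::aggregate(deaths ~ age_class, data = d, FUN = sum)
  total <- sum(counts$deaths)
  if (total == 0) {
    return(tibble::tibble(median_lifespan = NA_real_,
                          life_expectancy = NA_real_,
                          max_lifespan = NA_real_, n_deaths = 0))
  }
  cum <- cumsum(counts$deaths)
  med <- counts$age_class[which(cum >= total / 2)[1L]]
  lt <- life_table_observed(x, windows = windows)
  tibble::tibble(
    median_lifespan = as.numeric(med),
    life_expectancy = sum(lt$survivorship, na.rm = TRUE),
    max_lifespan = max(counts$age_class[counts$deaths > 0]),
    n_deaths = total
  )
}

# Linear interpolation of the age at which survivorship crosses 0.5. If the
# curve never crosses within the modeled ages, the age cap is returned: no
# lifespan can exceed the final age class.
survivorship_median <- function(ages, l) {
  ok <- !is.na(l)
  ages <- ages[ok]
  l <- l[ok]
  below <- which(l <= 0.5)
  if (!length(below)) return(max(ages))
  i <- below[1L]
  if (i == 1L) return(ages[1L])
  if (l[i - 1L] == l[i]) return(ages[i])
  ages[i - 1L] + (ages[i] - ages[i - 1L]) * (l[i - 1L] - 0.5) /
    (l[i - 1L] - l[i])
}

# --- plotting --------------------------------------------------------------

#' Plot life-history curves
#'
#' @param object A `life_history_curves` tibble.
#' @param scale_fertility Factor applied to fertility for display (the
#'   stored phenotype lives on `[0, 0.5]`; plots conventionally show it
#'   doubled).
#' @param ... Unused.
#' @return A ggplot object faceted into mortality, fertility and
#'   survivorship panels.
#' @export
autoplot.life_history_curves <- function(object, scale_fertility = 2, ...) {
  df <- tidyr::pivot_longer(
    dplyr::mutate(object, fertility = .data$fertility * scale_fertility),
    c("mortality", "survivorship", "fertility"),
    names_to = "curve", values_to = "value"
  )
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age_class, y = .data$value,
                                   colour = .data$flavor)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~curve, scales = "free_y") +
    ggplot2::labs(x = "age class (steps)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a site frequency spectrum
#'
#' @param object An `sfs_result`.
#' @param color_by `"none"`, `"age_class"` or `"effect"` (sign of the
#'   fitness effect under the current drift map).
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sfs_result <- function(object, color_by = "none", bins = 10, ...) {
  color_by <- match.arg(color_by, c("none", "age_class", "effect"))
  loci <- object$loci
  loci <- loci[loci$frequency > 0 & loci$frequency < 1, ]
  p <- ggplot2::ggplot(loci, ggplot2::aes(x = .data$frequency))
  p <- switch(color_by,
    none = p + ggplot2::geom_histogram(bins = bins),
    age_class = p + ggplot2::geom_histogram(
      ggplot2::aes(fill = .data$age_class), bins = bins),
    effect = p + ggplot2::geom_histogram(
      ggplot2::aes(fill = .data$effect > 0), bins = bins) +
      ggplot2::labs(fill = "beneficial")
  )
  p + ggplot2::labs(x = "allele frequency", y = "variant count") +
    ggplot2::theme_minimal()
}

#' Plot the population-size series of a run
#'
#' @param object A `sim_run`.
#' @param ... Unused.
#' @return A ggplot object with the per-step population size and the
#'   carrying capacity as a dashed line.
#' @export
autoplot.sim_run <- function(object, ...) {
  ggplot2::ggplot(object$ledgers$popsize,
                  ggplot2::aes(x = .data$step, y = .data$n)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$config$K, linetype = "dashed") +
    ggplot2::labs(x = "step", y = "population size") +
    ggplot2::theme_minimal()
}

# --- output tree -----------------------------------------------------------

#' Write a run's ledgers and dumps to a directory
#'
#' Writes the tidy ledgers as CSV (`deaths.csv`: one row per window x age
#' class x cause with stable cause strings; `births.csv`; `demography.csv`;
#' `popsize.csv`: two columns; `steps.csv`), the final genotype dump as a
#' wide CSV (one row per haplotype, columns = bit positions) with a layout
#' sidecar (`genotype_layout.csv`: bit, trait, age class, effect size,
#' beneficial direction), and a `metadata.json` with the configuration
#' echo, seed and version string.
#'
#' @param run A `sim_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  wr(run$ledgers$deaths, "deaths.csv")
  wr(run$ledgers$births, "births.csv")
  wr(run$ledgers$demography, "demography.csv")
  wr(run$ledgers$popsize, "popsize.csv")
  wr(run$ledgers$steps, "steps.csv")
  if (!is.null(run$ledgers$births_detail)) {
    wr(run$ledgers$births_detail, "births_detail.csv")
  }

  snap <- run$genotypes[[length(run$genotypes)]]
  haps <- as.data.frame(snap$haplotypes)
  names(haps) <- paste0("bit", run$architecture$layout$bit)
  wr(haps, "genotypes.csv")
  layout <- run$architecture$layout
  layout$beneficial_allele <- snap$drift
  wr(layout, "genotype_layout.csv")

  meta <- run$metadata
  meta$runtime_sec <- NULL # wall-clock time would break byte-identity
  meta$config <- config_to_list(run$config)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(dir)
}

# Configuration as plain nested lists for a JSON echo.
config_to_list <- function(cfg) {
  rapply(unclass(cfg), f = function(x) x, how = "list")
}
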