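#' Seed a population with full-length insertions
#'
#' Places `n_fl` full-length (FL) TE insertions at distinct uniformly random
#' genomic sites, each on one haplotype of one randomly chosen individual, so
#' every insertion starts at population frequency `1/2N`.
#'
#' @param config A [sim_config()].
#' @param n_fl Number of FL insertions; defaults to `config$n_fl`.
#' @return A `te_population`: a list with `insertions` (tibble with columns
#'   `individual`, `haplotype`, `chrom`, `pos`, `variant`; `variant = 0` is
#'   FL), `variants` (tibble `id`, `start`, `end` of ID breakpoints) and `N`.
#' @examples
#' set.seed(1)
#' pop <- init_population(sim_config(N = 50), n_fl = 20)
#' nrow(pop$insertions)
#' @export
init_population <- function(config, n_fl = config$n_fl) {
  stopifnot(inherits(config, "sim_config"), n_fl >= 0)
  mat <- cpp_init_population(config$N, config$chrom_len, as.integer(n_fl))
  new_te_population(mat, empty_variants(), config$N)
}

new_te_population <- function(ins_mat, variants, N) {
  structure(
    list(insertions = as_tibble(ins_mat),
         variants = variants,
         N = as.integer(N)),
    class = "te_population"
  )
}

empty_variants <- function() {
  tibble(id = integer(), start = integer(), end = integer())
}

variants_to_tbl <- function(vm) as_tibble(vm)

variants_to_mat <- function(tbl) {
  m <- as.matrix(tbl[, c("id", "start", "end")])
  storage.mode(m) <- "integer"
  m
}

ins_to_mat <- function(tbl) {
  m <- as.matrix(tbl[, c("individual", "haplotype", "chrom", "pos", "variant")])
  storage.mode(m) <- "integer"
  m
}

#' @export
print.te_population <- function(x, ...) {
  cat(sprintf("<te_population> N = %d, %d TE copies (%d ID), %d ID variants recorded\n",
              x$N, nrow(x$insertions), sum(x$insertions$variant > 0),
              nrow(x$variants)))
  invisible(x)
}

#' Is the TE active in an individual?
#'
#' Under the trap model the TE is active in a diploid that carries at least
#' one FL insertion anywhere in the genome and no insertion (FL or ID) inside
#' a piRNA cluster; a single cluster insertion, or the absence of FL copies,
#' silences the TE.
#'
#' @param individual Tibble of one individual's insertions (columns
#'   `haplotype`, `chrom`, `pos`, `variant`).
#' @param config A [sim_config()] defining genome layout and cluster windows.
#' @return `TRUE` if the TE is active in this individual.
#' @export
is_active <- function(individual, config) {
  mat <- ind_to_mat(individual)
  cpp_is_active(mat, cfg_for_engine(config))
}

ind_to_mat <- function(individual) {
  individual <- as_tibble(individual)
  if (!"individual" %in% names(individual)) {
    individual$individual <- 1L
  }
  ins_to_mat(individual)
}

#' Form a haploid gamete from a diploid parent
#'
#' Per chromosome, the crossover count is Poisson with mean
#' `rr / 100 * length_Mb`, crossover positions are uniform, and chromosomes
#' assort independently; the returned haplotype is a mosaic of the two
#' parental haplotypes.
#'
#' @inheritParams is_active
#' @return Tibble with columns `chrom`, `pos`, `variant`.
#' @export
make_gamete <- function(individual, config) {
  as_tibble(cpp_make_gamete(ind_to_mat(individual), cfg_for_engine(config)))
}

#' Transpose new copies into a gamete
#'
#' If the parent is active, a Poisson(`u * n / 2`) number of new insertions is
#' placed at uniform unoccupied sites of the gamete (`n` = parent's diploid
#' copy number). The template copy is drawn with per-copy weight `fl_id` for
#' FL and `1 - fl_id` for ID copies. An FL template yields a fresh ID variant
#' with probability `c` (two distinct uniform breakpoints, ordered); an ID
#' template propagates its breakpoints unchanged. Gametes of inactive parents
#' are returned untouched.
#'
#' @inheritParams is_active
#' @param gamete Tibble as returned by [make_gamete()].
#' @param variants Tibble of known ID variants (`id`, `start`, `end`).
#' @return List with updated `gamete` and `variants`.
#' @export
transpose_into_gamete <- function(individual, gamete, config,
                                  variants = empty_variants()) {
  gm <- as.matrix(as_tibble(gamete)[, c("chrom", "pos", "variant")])
  storage.mode(gm) <- "integer"
  res <- cpp_transpose_into_gamete(ind_to_mat(individual), gm,
                                   variants_to_mat(variants),
                                   cfg_for_engine(config))
  list(gamete = as_tibble(res$gamete), variants = variants_to_tbl(res$variants))
}

#' Advance a population by one generation
#'
#' Executes one full generation: fitness-weighted parent sampling (fitness
#' `max(0, 1 - x * n)`; uniform when `x = 0`; self-pairing excluded), one
#' gamete from each of the two parents with recombination, transposition into
#' gametes of active parents, and zygote formation. The population size is
#' exactly `N` afterwards.
#'
#' @param population A `te_population`.
#' @param config A [sim_config()].
#' @return Updated `te_population` with an attribute `stats` (named vector
#'   `copy_number`, `fraction_id`, `cluster_insertions`, `n_variants`).
#' @export
step_generation <- function(population, config) {
  res <- cpp_step_generation(ins_to_mat(population$insertions),
                             variants_to_mat(population$variants),
                             cfg_for_engine(config))
  out <- new_te_population(res$population, variants_to_tbl(res$variants),
                           config$N)
  attr(out, "stats") <- res$stats
  out
}

#' Move migrants between two populations
#'
#' Copies `m` individuals, sampled without replacement from the source, over
#' `m` uniformly chosen individuals of the target. Both populations keep their
#' census size; the source is unchanged.
#'
#' @param source,target `te_population` objects of equal size.
#' @param m Number of migrants (`0 <= m <= N`).
#' @return List with updated `source` and `target`.
#' @export
migrate <- function(source, target, m) {
  if (m > source$N) abort("migrant count m exceeds population size N")
  if (source$N != target$N) abort("source and target must have equal size N")
  if (m == 0) return(list(source = source, target = target))
  res <- cpp_migrate(ins_to_mat(source$insertions),
                     ins_to_mat(target$insertions), as.integer(m), source$N)
  vars <- dplyr::bind_rows(source$variants, target$variants) |>
    dplyr::distinct(.data$id, .keep_all = TRUE) |>
    dplyr::arrange(.data$id)
  list(source = new_te_population(res$source, vars, source$N),
       target = new_te_population(res$target, vars, target$N))
}

#' Run a TE invasion
#'
#' Runs the full forward simulation described by `config`: a single-population
#' invasion when `config$n_pops == 1`, otherwise a 1D stepping-stone invasion
#' in which, every `migration_interval` generations, `migration_m` migrants
#' are copied from the most recently invaded population into the next naive
#' one. `run_single_invasion()` and `run_stepping_stone()` are explicit
#' entry points that check the corresponding configuration.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; overrides `config$seed`. Identical seed and
#'   config give bit-identical results.
#' @return An `invasion` object: list with
#'   \describe{
#'     \item{records}{tibble `generation`, `population`, `copy_number` (mean
#'       diploid copies), `fraction_id`, `cluster_insertions`, `n_variants`.}
#'     \item{fingerprints}{for each sampled generation, a list (one tibble per
#'       population) of ID counts: `variant`, `start`, `end`, `count`,
#'       `total_copies`.}
#'     \item{variants}{breakpoints of every ID variant ever created.}
#'     \item{populations}{final `te_population` objects.}
#'   }
#' @examples
#' cfg <- sim_config(N = 100, n_fl = 30, generations = 50, conversion = 0.05)
#' inv <- run_single_invasion(cfg, seed = 1)
#' tail(inv$records)
#' @export
run_invasion <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_run_invasion(cfg_for_engine(config), config$n_pops, config$n_fl,
                          config$generations, config$record_every,
                          config$migration_interval, config$migration_m,
                          config$sample_generations)
  vars <- variants_to_tbl(res$variants)
  structure(
    list(
      records = as_tibble(res$records),
      fingerprints = lapply(res$fingerprints, function(gen_list) {
        lapply(gen_list, as_tibble)
      }),
      variants = vars,
      populations = lapply(res$populations, new_te_population,
                           variants = vars, N = config$N),
      config = config, seed = seed
    ),
    class = "invasion"
  )
}

#' @rdname run_invasion
#' @export
run_single_invasion <- function(config, seed = config$seed) {
  if (config$n_pops != 1) abort("run_single_invasion() needs n_pops = 1")
  run_invasion(config, seed)
}

#' @rdname run_invasion
#' @export
run_stepping_stone <- function(config, seed = config$seed) {
  if (config$n_pops < 2) abort("run_stepping_stone() needs n_pops >= 2")
  if (config$migration_interval < 1 || config$migration_m < 1) {
    abort("stepping-stone runs need a positive migration interval and size")
  }
  run_invasion(config, seed)
}

#' @export
print.invasion <- function(x, ...) {
  fin <- dplyr::filter(x$records, .data$generation == max(.data$generation))
  cat(sprintf("<invasion> %d population(s), %d generations, %d ID variants created\n",
              x$config$n_pops, x$config$generations, nrow(x$variants)))
  cat(sprintf("  final mean copy number %.2f, mean fraction ID %.3f\n",
              mean(fin$copy_number), mean(fin$fraction_id, na.rm = TRUE)))
  invisible(x)
}

#' ID fingerprint of a population
#'
#' Tabulates, for each distinct ID (merged by identical breakpoints), the
#' number of copies carrying it and its frequency among all TE copies of the
#' population. The FL frequency is the complement `1 - sum(frequency)`.
#'
#' @param population A `te_population`, or a tibble of raw fingerprint counts
#'   as stored in `invasion$fingerprints` (columns `variant`, `start`, `end`,
#'   `count`, `total_copies`).
#' @param sample_id Label used in the `sample_id` column.
#' @return Tibble with columns `sample_id`, `start`, `end`, `support`
#'   (carrier copy count), `frequency`.
#' @export
population_fingerprint <- function(population, sample_id = "pop1") {
  counts <- if (inherits(population, "te_population")) {
    ins <- population$insertions
    if (nrow(ins) == 0) {
      abort("fingerprint undefined: population carries no TE copies")
    }
    ids <- dplyr::filter(ins, .data$variant > 0) |>
      dplyr::count(.data$variant, name = "count") |>
      left_join(population$variants, by = c(variant = "id"))
    mutate(ids, total_copies = nrow(ins))
  } else {
    as_tibble(population)
  }
  counts |>
    group_by(.data$start, .data$end) |>
    summarise(support = sum(.data$count),
              total = .data$total_copies[1], .groups = "drop") |>
    mutate(sample_id = sample_id, frequency = .data$support / .data$total) |>
    select("sample_id", "start", "end", "support", "frequency") |>
    arrange(.data$start, .data$end)
}

#' Fingerprint table of a finished run
#'
#' Collects the per-population ID fingerprints of an [run_invasion()] result
#' at one sampled generation into the tab-separated fingerprint layout used by
#' the analysis pipeline. Populations without TE copies are skipped.
#'
#' @param invasion An `invasion` object.
#' @param generation Sampled generation; defaults to the last one.
#' @return Tibble with columns `sample_id`, `start`, `end`, `support`,
#'   `frequency`; sample ids are `pop1`, `pop2`, ...
#' @export
fingerprint_table <- function(invasion, generation = NULL) {
  stopifnot(inherits(invasion, "invasion"))
  gens <- names(invasion$fingerprints)
  if (length(gens) == 0) abort("run recorded no fingerprints")
  g <- if (is.null(generation)) gens[length(gens)] else as.character(generation)
  if (!g %in% gens) {
    abort(sprintf("generation %s was not sampled (available: %s)", g,
                  paste(gens, collapse = ", ")))
  }
  fps <- invasion$fingerprints[[g]]
  out <- imap(fps, function(fp, i) {
    if (nrow(fp) == 0) return(NULL)
    population_fingerprint(fp, sample_id = paste0("pop", i))
  })
  list_rbind(out[!vapply(out, is.null, logical(1))])
}
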