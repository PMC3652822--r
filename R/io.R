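# Synthetic CFU count tables, their CSV schema and metadata sidecars.
#
# Schema: time_h, cfu_total, cfu_normal, cfu_persister, replicate
# (the subpopulation columns are optional in files read back in).
# Metadata (generating parameters, noise model, seed, schema version)
# travels in a JSON sidecar next to the CSV, never in CSV comments.

COUNT_TABLE_SCHEMA_VERSION <- "1.0"

#' Measurement-noise model for synthetic count tables
#'
#' `"lognormal"` perturbs each count by `10^rnorm(0, sigma)` (multiplicative
#' plating noise on the log10 scale, the standard picture for serial
#' dilution/CFU counting); `"poisson_cfu"` draws colony counts as
#' `Poisson(count * plated_fraction) / plated_fraction`; `"none"` returns
#' the model means.
#'
#' @param kind `"lognormal"`, `"poisson_cfu"` or `"none"`.
#' @param sigma Log10-scale standard deviation (lognormal; default 0.1).
#' @param plated_fraction Dilution factor in (0, 1] (poisson_cfu).
#' @param seed Integer seed; mandatory unless `kind = "none"` so that every
#'   generated table is exactly reproducible.
#' @return Object of class `"noise_model"`.
#' @export
noise_model <- function(kind = c("lognormal", "poisson_cfu", "none"),
                        sigma = 0.1, plated_fraction = 1, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(sigma), sigma >= 0,
            is.numeric(plated_fraction),
            plated_fraction > 0, plated_fraction <= 1)
  if (kind != "none" && is.null(seed))
    stop("a seed is mandatory for stochastic noise models", call. = FALSE)
  structure(list(kind = kind, sigma = sigma,
                 plated_fraction = plated_fraction,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "noise_model")
}

as_noise_model <- function(noise) {
  if (is.null(noise)) return(noise_model("none"))
  if (!inherits(noise, "noise_model"))
    stop("expected a 'noise_model' object", call. = FALSE)
  noise
}

# Evaluate an expression with a private RNG stream, restoring the caller's.
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

apply_noise <- function(x, noise) {
  switch(noise$kind,
         none = x,
         lognormal = x * 10^stats::rnorm(length(x), 0, noise$sigma),
         poisson_cfu = stats::rpois(length(x),
                                    x * noise$plated_fraction) /
           noise$plated_fraction)
}

new_count_table <- function(df, metadata) {
  structure(df, class = c("count_table", "data.frame"), metadata = metadata)
}

#' Metadata of a count table
#'
#' @param table A `count_table`.
#' @return The metadata list (generating parameters, noise model, seed,
#'   schema version) or `NULL`.
#' @export
count_table_metadata <- function(table) attr(table, "metadata")

make_count_rows <- function(traj, noise, replicate = 1L) {
  df <- as.data.frame(traj)
  data.frame(time_h = df$time_h,
             cfu_total = apply_noise(df$total, noise),
             cfu_normal = apply_noise(df$n, noise),
             cfu_persister = apply_noise(df$p, noise),
             replicate = replicate,
             phase_label = df$phase_label)
}

#' Generate synthetic shift-experiment count curves
#'
#' Simulates a two-phase shift protocol (e.g. 15 h of growth followed by
#' 15 h of antibiotic stress) with the exact model dynamics and overlays
#' measurement noise independently on every observation (total, normal and
#' persister counts are "plated" independently). All parameters and the
#' seed are recorded in the table metadata; a fixed seed reproduces the
#' table exactly.
#'
#' @param env_pre,env_post [env_params()] of the pre- and post-shift
#'   environments.
#' @param t_pre,t_post Phase durations (hours).
#' @param state0 Initial [population_state()].
#' @param points_per_phase Observations per phase (>= 2).
#' @param noise A [noise_model()] (default: none).
#' @param n_replicates Number of independent noisy replicates.
#' @return A `count_table`: data frame with columns `time_h`, `cfu_total`,
#'   `cfu_normal`, `cfu_persister`, `replicate`, `phase_label` and a
#'   metadata attribute.
#' @export
generate_shift_curves <- function(env_pre, env_post, t_pre, t_post, state0,
                                  points_per_phase = 30L, noise = NULL,
                                  n_replicates = 1L) {
  noise <- as_noise_model(noise)
  stopifnot(points_per_phase >= 2L, n_replicates >= 1L)
  traj <- simulate_protocol(list(list(env = env_pre, duration = t_pre),
                                 list(env = env_post, duration = t_post)),
                            state0, samples_per_phase = points_per_phase)
  gen <- function() do.call(rbind, lapply(seq_len(n_replicates), function(r)
    make_count_rows(traj, noise, replicate = r)))
  df <- if (noise$kind == "none") gen() else with_private_seed(noise$seed, gen())
  rownames(df) <- NULL
  meta <- list(schema_version = COUNT_TABLE_SCHEMA_VERSION,
               kind = "shift",
               env_pre = unclass(env_pre), env_post = unclass(env_post),
               t_pre = t_pre, t_post = t_post,
               state0 = unclass(as_population_state(state0)),
               points_per_phase = points_per_phase,
               n_replicates = n_replicates,
               noise = unclass(noise))
  new_count_table(df, meta)
}

#' Generate synthetic periodic-environment count curves
#'
#' Periodic analog of [generate_shift_curves()]: `n_cycles` repetitions of
#' the growth/stress cycle of a [cycle_spec()].
#'
#' @param spec A [cycle_spec()].
#' @param n_cycles Number of cycles.
#' @param state0 Initial [population_state()].
#' @param points_per_phase Observations per phase.
#' @param noise A [noise_model()] (default: none).
#' @param n_replicates Number of independent noisy replicates.
#' @return A `count_table` (see [generate_shift_curves()]).
#' @export
generate_periodic_curves <- function(spec, n_cycles, state0,
                                     points_per_phase = 20L, noise = NULL,
                                     n_replicates = 1L) {
  spec <- as_cycle_spec(spec)
  noise <- as_noise_model(noise)
  stopifnot(n_cycles >= 1L, points_per_phase >= 2L, n_replicates >= 1L)
  phases <- rep(list(list(env = spec$env_g, duration = spec$t_g),
                     list(env = spec$env_s, duration = spec$t_s)),
                n_cycles)
  traj <- simulate_protocol(phases, state0,
                            samples_per_phase = points_per_phase)
  gen <- function() do.call(rbind, lapply(seq_len(n_replicates), function(r)
    make_count_rows(traj, noise, replicate = r)))
  df <- if (noise$kind == "none") gen() else with_private_seed(noise$seed, gen())
  rownames(df) <- NULL
  meta <- list(schema_version = COUNT_TABLE_SCHEMA_VERSION,
               kind = "periodic",
               env_g = unclass(spec$env_g), env_s = unclass(spec$env_s),
               t_g = spec$t_g, t_s = spec$t_s, n_cycles = n_cycles,
               state0 = unclass(as_population_state(state0)),
               points_per_phase = points_per_phase,
               n_replicates = n_replicates,
               noise = unclass(noise))
  new_count_table(df, meta)
}

validate_count_table <- function(df, file = "count table") {
  if (!("time_h" %in% names(df)))
    stop(file, ": missing required column 'time_h'", call. = FALSE)
  if (!("cfu_total" %in% names(df)))
    stop(file, ": missing required column 'cfu_total'", call. = FALSE)
  count_cols <- intersect(c("cfu_total", "cfu_normal", "cfu_persister"),
                          names(df))
  for (cc in count_cols) {
    bad <- which(!is.na(df[[cc]]) & df[[cc]] < 0)
    if (length(bad))
      stop(file, ": negative count in column '", cc, "' at row ", bad[1L],
           call. = FALSE)
  }
  if (!("replicate" %in% names(df))) df$replicate <- 1L
  for (r in unique(df$replicate)) {
    tt <- df$time_h[df$replicate == r]
    if (is.unsorted(tt, strictly = TRUE))
      stop(file, ": 'time_h' must be strictly increasing within replicate ",
           r, call. = FALSE)
  }
  df
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a count table as CSV plus JSON metadata sidecar
#'
#' The CSV is comma-separated, UTF-8, header required, `.` decimal
#' separator; metadata is written to `<path>.json`. Reading validates the
#' schema strictly (required columns, non-negative counts, strictly
#' increasing times within each replicate) and names the offending
#' column/row in errors.
#'
#' @param table A `count_table` (or schema-conformant data frame).
#' @param path CSV file path.
#' @return `write_count_table()` returns `path` invisibly;
#'   `read_count_table()` returns a `count_table` (metadata attached when
#'   the sidecar exists).
#' @export
write_count_table <- function(table, path) {
  df <- validate_count_table(as.data.frame(table))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  meta <- count_table_metadata(table)
  if (!is.null(meta))
    jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- validate_count_table(df, file = path)
  meta <- if (file.exists(sidecar_path(path)))
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  else NULL
  new_count_table(df, meta)
}
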