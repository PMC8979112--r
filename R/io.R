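#' Read a compound-by-sample peak-area table
#'
#' Delimited text (comma) with required header columns `compound_id`,
#' `species`, `replicate`, `area`; optional `mz`, `rt`, `name`. Rows with a
#' missing or negative area are rejected with line-numbered diagnostics
#' (attached as the `"rejected"` attribute and reported via a warning);
#' duplicate `(compound_id, species, replicate)` keys are an error.
#'
#' @param path Path to the CSV file.
#' @return A `peak_area_matrix` data frame of the valid rows.
#' @export
read_peak_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("compound_id", "species", "replicate", "area")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("peak table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  line_no <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- is.na(df$area) | df$area < 0 | is.na(df$compound_id) |
    df$compound_id == "" | is.na(df$replicate)
  if (any(bad)) {
    msgs <- sprintf("line %d: %s", line_no[bad],
                    ifelse(is.na(df$area[bad]) | df$area[bad] < 0,
                           "missing or negative area",
                           "missing compound_id or replicate"))
    warning("rejected ", sum(bad), " malformed row(s):\n  ",
            paste(msgs, collapse = "\n  "), call. = FALSE)
  }
  out <- df[!bad, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("no valid rows in peak table '", path, "'", call. = FALSE)
  key <- paste(out$compound_id, out$species, out$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- out[duplicated(key), c("compound_id", "species", "replicate")]
    stop("duplicate (compound_id, species, replicate) key(s): ",
         paste(apply(dup, 1, paste, collapse = "/"), collapse = ", "),
         call. = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "rejected") <- line_no[bad]
  class(out) <- c("peak_area_matrix", "data.frame")
  out
}

#' @rdname read_peak_table
#' @param matrix A `peak_area_matrix`.
#' @export
write_peak_table <- function(matrix, path) {
  utils::write.csv(as.data.frame(matrix), path, row.names = FALSE)
  invisible(path)
}

#' Read / write serial concentration profiles as delimited text
#'
#' Long-format CSV with header `compound_id, time_h, value, below_lloq`.
#'
#' @param profiles A list of [concentration_profile()]s.
#' @param path File path.
#' @return `write_profiles` returns `path` invisibly; `read_profiles`
#'   returns a named list of `concentration_profile`s.
#' @export
write_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p)
    data.frame(compound_id = p$compound_id, time_h = p$times,
               value = p$values, below_lloq = p$below_lloq))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path)
  required <- c("compound_id", "time_h", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("profile file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (is.null(df$below_lloq)) df$below_lloq <- FALSE
  out <- lapply(split(df, df$compound_id), function(d) {
    d <- d[order(d$time_h), ]
    concentration_profile(d$time_h, d$value, d$compound_id[1],
                          below_lloq = as.logical(d$below_lloq))
  })
  out[unique(df$compound_id)]
}

#' Default pipeline configuration
#'
#' Study-design defaults for a fully simulated run: the 12-point 0-24 h
#' schedule, a 480 uL pool at 0.1 uL increments, the default synthetic
#' panel across human/rat/mouse, triplicate pooled measurements with 10%
#' multiplicative assay noise, and the screening thresholds r > 0.8,
#' p < 0.001 over the top 10 compounds.
#'
#' @param seed Integer seed recorded in, and driving, the whole run.
#' @return A named list understood by [run_pipeline()]; any element can be
#'   overridden before the run.
#' @export
default_config <- function(seed = 1L) {
  list(times_h = c(0, 0.25, 0.5, 1, 2, 3, 4, 6, 8, 10, 12, 24),
       total_volume_uL = 480, rounding_increment_uL = 0.1,
       species = c("human", "rat", "mouse"), screen_species = "human",
       replicates = 3, cv = 0.1, lloq = 0.005, response_factor = 1000,
       r_threshold = 0.8, p_threshold = 0.001, top_k = 10, top_n = 10,
       seed = as.integer(seed))
}

#' Run the full pooled-AUC screening pipeline
#'
#' One orchestrated pass from a configuration to a Q-marker report:
#' pooling design, simulated (or supplied) pooled peak areas, serial
#' pooled-vs-trapezoid method comparisons, per-species exposure ranking,
#' cross-species shares of the screening species' top-N set, Pearson
#' correlation of the top compounds against the reference candidate, and
#' Q-marker selection. Deterministic given the seed.
#'
#' @param config A list as from [default_config()], or a path to a YAML
#'   document with the same keys. If `peak_table` (a path) is present the
#'   pooled areas are read from it instead of simulated; otherwise the
#'   synthetic panel is used.
#' @param out_dir Optional directory; when given, all tables plus a
#'   human-readable `summary.txt` are written there (floats at full
#'   precision, percentages rounded only in the summary).
#' @return An object of class `"aucpool_run"` with elements `design`,
#'   `peak_table`, `comparisons`, `exposure`, `shares`, `correlations`,
#'   `qmarker`, and `provenance` (config, seed, package version).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- default_config()
  for (key in names(defaults))
    if (is.null(config[[key]])) config[[key]] <- defaults[[key]]
  if (is.null(config$seed)) stop("config must carry a seed", call. = FALSE)
  seed <- as.integer(config$seed)

  sched <- sampling_schedule(unlist(config$times_h))
  design <- pooling_volumes(sched, config$total_volume_uL,
                            config$rounding_increment_uL)
  panel <- default_panel()
  assay <- assay_model(response_factor = config$response_factor,
                       cv = config$cv, lloq = config$lloq)

  if (!is.null(config$peak_table)) {
    peak_tab <- read_peak_table(config$peak_table)
    comparisons <- NULL
    serial <- NULL
  } else {
    peak_tab <- simulate_cohort(config$species, panel, sched, assay,
                                config$replicates, seed, design)
    # Serial (traditional-method) arm in the screening species: noisy
    # triplicate serial profiles per compound, for method comparison and
    # for the correlation screen.
    serial <- list()
    truth <- panel_profiles(panel, config$screen_species, as.numeric(sched))
    idx <- 0L
    comparisons <- do.call(rbind, lapply(names(truth), function(cid) {
      # The two arms are physically distinct measurements: independent
      # noise draws for the serial (traditional) and pooled replicates.
      reps <- lapply(seq_len(2L * config$replicates), function(r) {
        idx <<- idx + 1L
        apply_assay(truth[[cid]], assay, derive_seed(seed + 1L, idx))
      })
      serial_reps <- reps[seq_len(config$replicates)]
      pooled_reps <- reps[config$replicates + seq_len(config$replicates)]
      mean_values <- Reduce(`+`, lapply(serial_reps, effective_values)) /
        length(serial_reps)
      serial[[cid]] <<- concentration_profile(
        as.numeric(sched), mean_values, cid, "area")
      trad <- mean(vapply(serial_reps, function(p) trapezoid_auc(p)$value,
                          0))
      pooled <- mean(vapply(pooled_reps, function(p)
        pooled_auc(pool_concentration(p, design), sched, cid)$value, 0))
      # A compound fully below the LLOQ has traditional AUC 0: the percent
      # difference is undefined and reported as NA, not an abort.
      data.frame(compound_id = cid, species = config$screen_species,
                 auc_traditional = trad, auc_pooled = pooled,
                 percent_difference = if (trad > 0)
                   percent_difference(trad, pooled) else NA_real_)
    }))
  }

  expo <- exposure_table(peak_tab, sched,
                         reference_available = panel$reference_available)

  # Screen only compounds with measurable exposure: fully LLOQ-censored
  # compounds rank last with zero exposure and cannot be correlated.
  screen_tab <- expo[expo$species == config$screen_species &
                       expo$exposure > 0, , drop = FALSE]
  class(screen_tab) <- class(expo)
  attr(screen_tab, "span_h") <- attr(expo, "span_h")
  top_k <- min(config$top_k, nrow(screen_tab))
  top_ids <- screen_tab$compound_id[screen_tab$rank <= top_k]

  shares <- do.call(rbind, lapply(
    setdiff(unique(expo$species), config$screen_species), function(sp)
      data.frame(species = sp,
                 share_pct = species_share(top_ids, expo, species = sp))))

  correlations <- NULL
  qmarker <- NULL
  if (!is.null(serial)) {
    avail <- screen_tab[screen_tab$reference_available, , drop = FALSE]
    if (nrow(avail)) {
      ref_id <- avail$compound_id[which.min(avail$rank)]
      correlations <- lapply(setdiff(top_ids, ref_id), function(cid)
        correlate_profiles(serial[[cid]], serial[[ref_id]]))
    }
    qmarker <- select_qmarker(screen_tab, correlations,
                              config$r_threshold, config$p_threshold, top_k)
  }

  run <- structure(
    list(design = design, peak_table = peak_tab, comparisons = comparisons,
         exposure = expo, shares = shares, correlations = correlations,
         qmarker = qmarker,
         provenance = list(config = config, seed = seed,
                           package_version =
                             as.character(utils::packageVersion("aucpool")))),
    class = "aucpool_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_design(run$design, file.path(out_dir, "design.csv"))
  write_peak_table(run$peak_table, file.path(out_dir, "peak_table.csv"))
  utils::write.csv(as.data.frame(run$exposure),
                   file.path(out_dir, "exposure.csv"), row.names = FALSE)
  if (!is.null(run$comparisons))
    utils::write.csv(run$comparisons,
                     file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
  if (!is.null(run$shares))
    utils::write.csv(run$shares, file.path(out_dir, "shares.csv"),
                     row.names = FALSE)
  if (!is.null(run$correlations)) {
    cor_df <- do.call(rbind, lapply(run$correlations, function(x)
      data.frame(compound_id = x$compound_id,
                 reference_id = x$reference_id, r = x$r, p = x$p, n = x$n)))
    utils::write.csv(cor_df, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
  }
  if (!is.null(run$qmarker)) {
    qm <- run$qmarker
    yaml::write_yaml(
      list(candidate_id = qm$candidate_id,
           candidate_rank = qm$candidate_rank, pass = qm$pass,
           reason = qm$reason, thresholds = qm$thresholds,
           companions = if (is.null(qm$companions)) NULL else
             lapply(seq_len(nrow(qm$companions)), function(i)
               as.list(qm$companions[i, ])),
           seed = run$provenance$seed),
      file.path(out_dir, "qmarker.yaml"))
  }
  summary_path <- file.path(out_dir, "summary.txt")
  con <- file(summary_path, "w"); on.exit(close(con))
  sink(con); print(run); sink()
  invisible(out_dir)
}

#' @export
print.aucpool_run <- function(x, ...) {
  cat(sprintf("Pooled-AUC screening run (seed %d)\n", x$provenance$seed))
  cat(sprintf("  design: %d aliquots, total %g uL\n",
              length(x$design$volumes), x$design$total_volume))
  if (!is.null(x$comparisons))
    cat(sprintf("  method comparison (%s): max |pooled - trad| = %.2f%%\n",
                x$comparisons$species[1],
                max(x$comparisons$percent_difference, na.rm = TRUE)))
  for (sp in unique(x$exposure$species)) {
    k <- min(x$provenance$config$top_n, sum(x$exposure$species == sp))
    cat(sprintf("  %s: top %d compounds carry %.2f%% of exposure\n", sp, k,
                cumulative_fraction(x$exposure, k, species = sp)))
  }
  if (!is.null(x$shares))
    for (i in seq_len(nrow(x$shares)))
      cat(sprintf("  screening set carries %.2f%% of exposure in %s\n",
                  x$shares$share_pct[i], x$shares$species[i]))
  if (!is.null(x$qmarker)) {
    cat(sprintf("  Q-marker: %s (%s)\n",
                if (is.na(x$qmarker$candidate_id)) "none" else
                  x$qmarker$candidate_id,
                if (x$qmarker$pass) "all screening criteria met" else
                  x$qmarker$reason))
  }
  invisible(x)
}
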