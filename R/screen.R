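#' Ranked semi-quantitative exposure table
#'
#' Exposure of a compound is the mean of its replicate pooled areas times
#' the schedule span `t_n - t_0` — the pooled-sample AUC in area x hours.
#' Multiplying by the fixed span changes no rank but keeps the values on the
#' AUC scale. Compounds are ranked per species in descending exposure, ties
#' broken by compound id (ascending); cumulative fractions accumulate to
#' 100% within each species.
#'
#' @param matrix A `peak_area_matrix` (see [simulate_cohort()] /
#'   [read_peak_table()]): data frame with `compound_id`, `species`,
#'   `replicate`, `area`.
#' @param schedule The [sampling_schedule()] behind the pooled samples.
#' @param reference_available Character vector of compound ids obtainable as
#'   reference substances (flags the `reference_available` column).
#' @return An `exposure_table`: data frame with columns `compound_id`,
#'   `species`, `exposure`, `rank`, `cumulative_fraction` (percent),
#'   `reference_available`, ordered by species then rank.
#' @export
exposure_table <- function(matrix, schedule,
                           reference_available = character()) {
  needed <- c("compound_id", "species", "replicate", "area")
  missing_cols <- setdiff(needed, names(matrix))
  if (length(missing_cols))
    stop("peak-area matrix is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(matrix) == 0L) stop("peak-area matrix is empty", call. = FALSE)
  sched <- as_schedule(schedule)
  span <- max(sched) - min(sched)
  agg <- stats::aggregate(area ~ compound_id + species, data = matrix,
                          FUN = mean)
  agg$exposure <- agg$area * span
  out <- do.call(rbind, lapply(split(agg, agg$species), function(d) {
    if (sum(d$exposure) <= 0)
      stop("all exposures are zero for species '", d$species[1],
           "': nothing to rank", call. = FALSE)
    d <- d[order(-d$exposure, d$compound_id), ]
    d$rank <- seq_len(nrow(d))
    d$cumulative_fraction <- cumsum(d$exposure) / sum(d$exposure) * 100
    d
  }))
  out$reference_available <- out$compound_id %in% reference_available
  out <- out[order(out$species, out$rank),
             c("compound_id", "species", "exposure", "rank",
               "cumulative_fraction", "reference_available")]
  rownames(out) <- NULL
  attr(out, "span_h") <- span
  class(out) <- c("exposure_table", "data.frame")
  out
}

# Restrict an exposure table to one species, erroring on ambiguity.
one_species <- function(table, species) {
  stopifnot(inherits(table, "exposure_table"))
  present <- unique(table$species)
  if (is.null(species)) {
    if (length(present) > 1L)
      stop("table contains several species (",
           paste(present, collapse = ", "), "); pass 'species'",
           call. = FALSE)
    species <- present
  }
  sub <- table[table$species == species, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no rows for species '", species, "'", call. = FALSE)
  sub
}

#' Cumulative exposure fraction of the top-N compounds
#'
#' Share of total exposure (default) or of the compound count carried by the
#' `top_n` highest-ranked compounds of one species.
#'
#' @param table An [exposure_table()].
#' @param top_n Number of top-ranked compounds, `1 <= top_n <= K`.
#' @param species Species to evaluate; may be omitted for a single-species
#'   table.
#' @param basis `"exposure"` (fraction of summed exposure, the default) or
#'   `"count"` (fraction of the number of compounds).
#' @return Percentage in (0, 100].
#' @export
cumulative_fraction <- function(table, top_n, species = NULL,
                                basis = c("exposure", "count")) {
  basis <- match.arg(basis)
  sub <- one_species(table, species)
  if (top_n < 1 || top_n > nrow(sub))
    stop("'top_n' must be between 1 and ", nrow(sub), call. = FALSE)
  if (basis == "count") return(top_n / nrow(sub) * 100)
  sum(sub$exposure[sub$rank <= top_n]) / sum(sub$exposure) * 100
}

#' Cross-species share of a reference compound set
#'
#' How much of another species' total exposure (default) or compound count
#' is carried by a given compound set — e.g. the human top-10 evaluated in
#' rat or mouse. Compounds absent from the other species contribute zero.
#'
#' @param reference_compounds Non-empty character vector of compound ids.
#' @param table The other species' [exposure_table()].
#' @param species Species to evaluate within `table` (optional for a
#'   single-species table).
#' @param basis `"exposure"` or `"count"`, as in [cumulative_fraction()].
#' @return Percentage in \[0, 100\].
#' @export
species_share <- function(reference_compounds, table, species = NULL,
                          basis = c("exposure", "count")) {
  basis <- match.arg(basis)
  if (length(reference_compounds) == 0L)
    stop("'reference_compounds' must be non-empty", call. = FALSE)
  sub <- one_species(table, species)
  sel <- sub$compound_id %in% reference_compounds
  if (basis == "count") return(sum(sel) / nrow(sub) * 100)
  sum(sub$exposure[sel]) / sum(sub$exposure) * 100
}

#' Time-percentage profile
#'
#' Each time point's value as a percentage of the profile's total, so that
#' profiles of compounds on very different absolute scales become
#' shape-comparable. The output is invariant to overall scaling of the
#' input and sums to 100.
#'
#' @param profile A [concentration_profile()] with positive total.
#' @return A [concentration_profile()] in `"%"` units.
#' @export
percent_profile <- function(profile) {
  stopifnot(inherits(profile, "concentration_profile"))
  v <- effective_values(profile)
  total <- sum(v)
  if (total <= 0)
    stop("profile total is zero; percentage profile undefined", call. = FALSE)
  concentration_profile(profile$times, v / total * 100, profile$compound_id,
                        "%", profile$below_lloq)
}

#' Pearson correlation between two time profiles
#'
#' Product-moment correlation of two compounds' time courses, by default on
#' their time-percentage profiles (shape correlation, insensitive to
#' absolute response); the two-sided p-value comes from the t statistic
#' `r * sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom
#' (`stats::cor.test`). Symmetric in its arguments.
#'
#' @param profile,reference [concentration_profile()]s on identical times,
#'   at least 3 points, neither constant.
#' @param normalize Correlate [percent_profile()]s (default `TRUE`) or raw
#'   values (`FALSE`).
#' @return A `correlation_result`: `compound_id`, `reference_id`, `r`, `p`,
#'   `n`.
#' @export
correlate_profiles <- function(profile, reference, normalize = TRUE) {
  stopifnot(inherits(profile, "concentration_profile"),
            inherits(reference, "concentration_profile"))
  if (length(profile$times) != length(reference$times) ||
      !isTRUE(all.equal(profile$times, reference$times)))
    stop("profiles must share the same time points", call. = FALSE)
  if (length(profile$times) < 3L)
    stop("need at least 3 time points for a correlation", call. = FALSE)
  if (normalize) {
    profile <- percent_profile(profile)
    reference <- percent_profile(reference)
  }
  x <- effective_values(profile); y <- effective_values(reference)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant profile: Pearson r undefined", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(compound_id = profile$compound_id,
                 reference_id = reference$compound_id,
                 r = unname(ct$estimate), p = ct$p.value, n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson '%s' vs '%s': r = %.4f, p = %.3g (n = %d)\n",
              x$compound_id, x$reference_id, x$r, x$p, x$n))
  invisible(x)
}

#' Select a quality-marker (Q-marker) candidate
#'
#' The candidate is the highest-ranked compound with an obtainable
#' reference substance; it qualifies when every other compound in the top
#' `top_k` correlates with it strongly (`r > r_threshold`) and significantly
#' (`p < p_threshold`). The report carries per-companion pass flags and
#' fails loudly — explicit flags and a reason — rather than silently when no
#' candidate exists or a correlation is missing. No multiple-testing
#' correction is applied; all p-values are recorded so users can apply their
#' own procedure.
#'
#' @param table A single-species [exposure_table()].
#' @param correlations List of `correlation_result`s of the other top-`k`
#'   compounds against the candidate (either argument order).
#' @param r_threshold Minimum Pearson r (exclusive), default 0.8.
#' @param p_threshold Maximum p-value (exclusive), default 0.001.
#' @param top_k Size of the screened head of the ranking, default 10
#'   (capped at the table size).
#' @return A `qmarker_report`: `candidate_id` (or `NA`), `candidate_rank`,
#'   `companions` (data frame with `compound_id`, `rank`, `r`, `p`,
#'   `pass_r`, `pass_p`, `pass`), `thresholds`, overall `pass`, `reason`.
#' @export
select_qmarker <- function(table, correlations, r_threshold = 0.8,
                           p_threshold = 0.001, top_k = 10) {
  sub <- one_species(table, NULL)
  if (r_threshold <= 0 || r_threshold >= 1 || p_threshold <= 0 ||
      p_threshold >= 1)
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  top_k <- min(top_k, nrow(sub))
  thresholds <- list(r_threshold = r_threshold, p_threshold = p_threshold,
                     top_k = top_k)
  avail <- sub[sub$reference_available, , drop = FALSE]
  if (nrow(avail) == 0L) {
    return(structure(list(candidate_id = NA_character_,
                          candidate_rank = NA_integer_,
                          companions = NULL, thresholds = thresholds,
                          pass = FALSE,
                          reason = "no compound has an obtainable reference substance"),
                     class = "qmarker_report"))
  }
  candidate <- avail[which.min(avail$rank), ]
  head_tab <- sub[sub$rank <= top_k & sub$compound_id != candidate$compound_id,
                  , drop = FALSE]
  find_cor <- function(cid) {
    for (cr in correlations) {
      ids <- c(cr$compound_id, cr$reference_id)
      if (setequal(ids, c(cid, candidate$compound_id))) return(cr)
    }
    NULL
  }
  comp <- do.call(rbind, lapply(seq_len(nrow(head_tab)), function(i) {
    cid <- head_tab$compound_id[i]
    cr <- find_cor(cid)
    if (is.null(cr))
      data.frame(compound_id = cid, rank = head_tab$rank[i], r = NA_real_,
                 p = NA_real_, pass_r = FALSE, pass_p = FALSE, pass = FALSE)
    else
      data.frame(compound_id = cid, rank = head_tab$rank[i], r = cr$r,
                 p = cr$p, pass_r = cr$r > r_threshold,
                 pass_p = cr$p < p_threshold,
                 pass = cr$r > r_threshold && cr$p < p_threshold)
  }))
  all_pass <- is.null(comp) || all(comp$pass)
  reason <- if (all_pass) "all criteria met" else {
    missing_r <- comp$compound_id[is.na(comp$r)]
    if (length(missing_r))
      paste("missing correlation for:", paste(missing_r, collapse = ", "))
    else
      paste("companions failing the correlation screen:",
            paste(comp$compound_id[!comp$pass], collapse = ", "))
  }
  structure(list(candidate_id = candidate$compound_id,
                 candidate_rank = candidate$rank, companions = comp,
                 thresholds = thresholds, pass = all_pass, reason = reason),
            class = "qmarker_report")
}

#' @export
print.qmarker_report <- function(x, ...) {
  cat("Q-marker screening report\n")
  if (is.na(x$candidate_id)) {
    cat("  candidate: none (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("  candidate: %s (exposure rank %d)\n", x$candidate_id,
              x$candidate_rank))
  cat(sprintf("  thresholds: r > %g, p < %g, top %d compounds\n",
              x$thresholds$r_threshold, x$thresholds$p_threshold,
              x$thresholds$top_k))
  if (!is.null(x$companions) && nrow(x$companions))
    print(x$companions, row.names = FALSE, digits = 4)
  cat(sprintf("  result: %s (%s)\n", if (x$pass) "PASS" else "FAIL",
              x$reason))
  invisible(x)
}

#' @export
summary.exposure_table <- function(object, top_n = 10, ...) {
  for (sp in unique(object$species)) {
    k <- min(top_n, sum(object$species == sp))
    cat(sprintf("%s: %d compounds; top %d carry %.1f%% of exposure\n", sp,
                sum(object$species == sp), k,
                cumulative_fraction(object, k, species = sp)))
  }
  invisible(object)
}
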