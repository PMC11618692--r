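# Standardized injury and survival coding of fish passage observations
# (NEN 8775 injury catalogue), plus cohort accounting.

#' The NEN 8775 injury code catalogue
#'
#' Class 1 is injury-free; class 2 codes are slight injuries; class 3
#' codes are severe injuries (which imply euthanasia and a "dead" survival
#' state).
#'
#' @return Data frame with columns `code` (numeric), `class` (integer
#'   part of the code) and `label`.
#' @export
injury_codes <- function() {
  data.frame(
    code = c(1, 2.1, 2.2, 2.3, 3.1, 3.2, 3.3, 3.4, 3.5, 3.6, 3.7),
    class = c(1L, 2L, 2L, 2L, 3L, 3L, 3L, 3L, 3L, 3L, 3L),
    label = c(
      "Injury free",
      "Minor superficial scratches",
      "Red or damaged eyes/fins",
      "Minor scale loss",
      "Scale loss (> 20% of body surface)",
      "Incisions, cuts, decapitation",
      "Fractures",
      "Heavily injured or missing eyes",
      "Heavily injured gills or gill covers",
      "Heavy contusion or bleeding",
      "Aberrant behavior"
    )
  )
}

parse_injury_codes <- function(s) {
  # ";"-separated code string per fish, "" or NA meaning injury-free
  if (is.na(s) || !nzchar(trimws(s))) return(numeric(0))
  as.numeric(strsplit(trimws(s), ";", fixed = TRUE)[[1L]])
}

#' Injury class of one fish from its set of injury codes
#'
#' The most severe injury class observed determines the class of the fish;
#' within that class the highest numeric code is reported as the worst
#' code (all codes are retained elsewhere for distribution tables). An
#' empty set codes as injury-free (class 1, code 1).
#'
#' @param codes Numeric vector of injury codes, or a `";"`-separated
#'   string (e.g. `"2.3;3.2"`).
#' @return List with `class` (1, 2 or 3) and `worst_code`.
#' @export
assign_injury_class <- function(codes) {
  if (is.character(codes)) codes <- parse_injury_codes(codes)
  if (length(codes) == 0L) return(list(class = 1L, worst_code = 1))
  cat_tbl <- injury_codes()
  if (!all(round(codes, 1) %in% cat_tbl$code)) {
    bad <- setdiff(round(codes, 1), cat_tbl$code)
    stop("UnknownCode: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cls <- max(floor(codes))
  list(class = as.integer(cls),
       worst_code = max(codes[floor(codes) == cls]))
}

#' Survival state of one fish
#'
#' A fish is coded dead (0) if it was observed dead or dying, if it
#' carries a severe (class 3) injury — severely injured fish are
#' euthanized — or if it died during the 24 h / 48 h delayed-mortality
#' holding period. Otherwise it is alive (1).
#'
#' @param condition `"alive"`, `"dying"` or `"dead"` (vectorized).
#' @param injury_class Injury class 1-3 (see [assign_injury_class()]).
#' @param delayed_dead_24h,delayed_dead_48h Logical delayed-mortality
#'   flags (default FALSE).
#' @return Integer vector: 1 = alive, 0 = dead.
#' @export
code_survival <- function(condition, injury_class,
                          delayed_dead_24h = FALSE, delayed_dead_48h = FALSE) {
  stopifnot(all(condition %in% c("alive", "dying", "dead")))
  dead <- condition %in% c("dead", "dying") | injury_class == 3L |
    (delayed_dead_24h %in% TRUE) | (delayed_dead_48h %in% TRUE)
  as.integer(!dead)
}

#' Code a raw fish table
#'
#' Adds `injury_class`, `worst_code` and `survival` columns to a fish
#' record table (see [read_fish()] for the expected columns).
#'
#' @param records Data frame of fish records with at least `condition`
#'   and `injury_codes` columns (plus optional delayed-mortality flags).
#' @return The table with the derived columns appended.
#' @export
code_fish <- function(records) {
  stopifnot(is.data.frame(records))
  coded <- lapply(records$injury_codes, assign_injury_class)
  records$injury_class <- vapply(coded, `[[`, integer(1), "class")
  records$worst_code <- vapply(coded, `[[`, numeric(1), "worst_code")
  d24 <- if ("delayed_dead_24h" %in% names(records)) records$delayed_dead_24h else FALSE
  d48 <- if ("delayed_dead_48h" %in% names(records)) records$delayed_dead_48h else FALSE
  records$survival <- code_survival(records$condition, records$injury_class,
                                    d24, d48)
  records
}

#' Reassign fish that lingered into the next scenario
#'
#' Fish intended for one scenario sometimes lingered in the pump cellar
#' and only passed during a later scenario; they are analysed under the
#' scenario at which they were actually observed. The intended scenario
#' is retained in `scenario_theoretical` for provenance and for start
#' counts.
#'
#' @param records Fish table with `scenario_theoretical` and
#'   `scenario_observed` columns.
#' @return The table with an analysis `scenario` column set to the
#'   observed scenario where known, the theoretical one otherwise.
#' @export
reassign_scenarios <- function(records) {
  obs <- records$scenario_observed
  theo <- records$scenario_theoretical
  records$scenario <- ifelse(!is.na(obs) & nzchar(as.character(obs)),
                             as.character(obs), as.character(theo))
  records
}

#' Remove extreme length outliers per species
#'
#' Lengths outside `Q1 - k*IQR` or `Q3 + k*IQR` (default k = 3, "extreme"
#' fences) are removed per species. Quantiles use the linear-interpolation
#' convention (R type 7). Fish without a length (not intact) are kept.
#'
#' @param records Coded fish table with `species` and `length_mm`.
#' @param k Fence multiplier (default 3).
#' @param qtype Quantile type passed to [stats::quantile()] (default 7).
#' @return List with `records` (filtered) and `n_removed` (named per
#'   species).
#' @export
remove_length_outliers <- function(records, k = 3, qtype = 7) {
  drop <- logical(nrow(records))
  removed <- integer(0)
  for (sp in unique(records$species)) {
    i <- which(records$species == sp & !is.na(records$length_mm))
    if (length(i) < 4L) { removed[sp] <- 0L; next }
    q <- stats::quantile(records$length_mm[i], c(0.25, 0.75), type = qtype,
                         names = FALSE)
    iqr <- q[2L] - q[1L]
    out <- records$length_mm[i] < q[1L] - k * iqr |
           records$length_mm[i] > q[2L] + k * iqr
    drop[i[out]] <- TRUE
    removed[sp] <- sum(out)
  }
  list(records = records[!drop, , drop = FALSE], n_removed = removed)
}

#' Cohort recapture table
#'
#' Per-scenario start counts (fish released), end counts (fish captured
#' after reassignment), recapture percentage, and mean length / mass of
#' intact fish; plus per-species overall rows (total captured over total
#' released). Per-scenario recapture can exceed 100 percent when fish
#' lingered from a previous scenario.
#'
#' @param records Coded fish table with `species`, `scenario` (analysis),
#'   `scenario_theoretical` columns.
#' @param starts Data frame with columns `species`, `scenario`, `n_start`:
#'   the number of fish released per intended scenario.
#' @return Data frame of class `cohort_table` with columns `species`,
#'   `scenario`, `n_start`, `n_end`, `recapture_pct`, `mean_length_mm`,
#'   `mean_mass_g`; overall rows have `scenario = "overall"`.
#' @export
recapture_table <- function(records, starts) {
  stopifnot(all(c("species", "scenario", "n_start") %in% names(starts)))
  rows <- list()
  for (r in seq_len(nrow(starts))) {
    sp <- starts$species[r]; sc <- starts$scenario[r]
    sub <- records[records$species == sp & records$scenario == sc, , drop = FALSE]
    rows[[r]] <- data.frame(
      species = sp, scenario = sc,
      n_start = starts$n_start[r], n_end = nrow(sub),
      recapture_pct = 100 * nrow(sub) / starts$n_start[r],
      mean_length_mm = mean(sub$length_mm, na.rm = TRUE),
      mean_mass_g = mean(sub$mass_g, na.rm = TRUE)
    )
  }
  tab <- do.call(rbind, rows)
  extra <- setdiff(unique(records$species), unique(starts$species))
  if (length(extra)) {
    stop("MissingStartCount: no start counts for species ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  for (sp in unique(starts$species)) {
    s_tot <- sum(starts$n_start[starts$species == sp])
    e_tot <- sum(records$species == sp)
    sub <- records[records$species == sp, , drop = FALSE]
    tab <- rbind(tab, data.frame(
      species = sp, scenario = "overall",
      n_start = s_tot, n_end = e_tot,
      recapture_pct = 100 * e_tot / s_tot,
      mean_length_mm = mean(sub$length_mm, na.rm = TRUE),
      mean_mass_g = mean(sub$mass_g, na.rm = TRUE)
    ))
  }
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Within-class injury code distribution
#'
#' For each injury class present, the percentage of observed injury codes
#' falling on each code, optionally per species. All codes a fish carries
#' count, not only the worst one.
#'
#' @param records Coded fish table with an `injury_codes` column.
#' @param by_species Split by species (default TRUE).
#' @return Data frame with columns `species` (if requested), `class`,
#'   `code`, `n`, `pct` (percentage within species x class).
#' @export
injury_distribution <- function(records, by_species = TRUE) {
  codes <- lapply(records$injury_codes, parse_injury_codes)
  n_each <- lengths(codes)
  long <- data.frame(
    species = rep(if (by_species) records$species else "all", n_each),
    code = unlist(codes)
  )
  if (nrow(long) == 0L) stop("EmptyClass: no injuries recorded", call. = FALSE)
  long$class <- floor(long$code)
  agg <- stats::aggregate(list(n = long$code),
                          by = list(species = long$species, class = long$class,
                                    code = long$code),
                          FUN = length)
  tot <- stats::aggregate(list(n_class = agg$n),
                          by = list(species = agg$species, class = agg$class),
                          FUN = sum)
  agg <- merge(agg, tot, by = c("species", "class"))
  agg$pct <- 100 * agg$n / agg$n_class
  agg$n_class <- NULL
  agg[order(agg$species, agg$class, -agg$pct), ]
}
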