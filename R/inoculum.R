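# Sequential community-assembly design: species fixture, inoculum
# allocation, colonization schedule.

#' The 26-species periphyton assembly table
#'
#' The packaged species parameter table behind the three-wave assembly
#' design: 27 records (26 distinct species; Cyclotella meneghiniana is
#' introduced with group A and again with group C) with phylum, logistic
#' rate constant `k` (OD685/h), maximum reached biomass `K_max` (max OD685),
#' published growth group (G1/G2/G3; "none" for the group-A pioneers),
#' starting inoculum (cells per mL) and the kinetics source
#' (`od685`, or `cell_count` for Nitzschia vermicularis, whose cell
#' morphology makes optical density unreliable).
#'
#' @return A tibble with columns `assembly_group`, `species`, `phylum`, `k`,
#'   `K_max`, `growth_group`, `inoculum`, `kinetics_source`.
#' @export
species_table <- function() {
  path <- system.file("extdata", "species_table.tsv", package = "periphytonr",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Default starting-inoculum densities (cells per mL)
#'
#' The inoculum rule of the assembly design: the fewer cells the faster a
#' species grows and the more biomass it reaches, so within each wave the
#' G1 default never exceeds G2, and G2 never exceeds G3. Group A pioneers
#' share one density.
#'
#' @return A tibble with columns `assembly_group`, `growth_group`,
#'   `inoculum`.
#' @export
default_inoculum <- function() {
  tibble::tribble(
    ~assembly_group, ~growth_group, ~inoculum,
    "A", "none", 125000,
    "B", "G1", 75000,
    "B", "G2", 125000,
    "B", "G3", 133000,
    "C", "G1", 65000,
    "C", "G2", 125000,
    "C", "G3", 300000
  )
}

#' Build the sequential-assembly inoculum plan
#'
#' Assigns each species its starting inoculum — a per-species override when
#' given, otherwise the default for its (assembly group, growth group) cell
#' — and summarises group totals plus the colonization schedule. With the
#' packaged [species_table()] and the single published override
#' (Pseudanabaena galeata at 190,000 cells/mL), the group totals are
#' 250,000 / 999,000 / 2,175,000 cells per mL for A / B / C.
#'
#' @param records Data frame with columns `species`, `assembly_group`, and
#'   (for groups B and C) `growth_group`.
#' @param defaults Default densities, as from [default_inoculum()].
#' @param overrides Optional named numeric vector, species name to cells/mL.
#' @param durations Colonization durations (days) passed to
#'   [build_schedule()].
#' @return An `inoculum_plan`: list with `records` (tibble: species,
#'   assembly_group, growth_group, inoculum), `group_totals` (tibble), and
#'   `schedule` (see [build_schedule()]).
#' @examples
#' plan <- allocate_inoculum(species_table(),
#'                           overrides = c("Pseudanabaena galeata" = 190000))
#' plan$group_totals
#' @export
allocate_inoculum <- function(records,
                              defaults = default_inoculum(),
                              overrides = NULL,
                              durations = c(A = 4, B = 14, C = 12)) {
  abort_if(!is.data.frame(records), "`records` must be a data frame.")
  if (nrow(records) == 0L) {
    return(structure(
      list(records = tibble::tibble(species = character(),
                                    assembly_group = character(),
                                    growth_group = character(),
                                    inoculum = numeric()),
           group_totals = tibble::tibble(assembly_group = character(),
                                         total = numeric()),
           schedule = build_schedule(durations)),
      class = "inoculum_plan"))
  }
  abort_if(!all(c("species", "assembly_group") %in% names(records)),
           "`records` needs `species` and `assembly_group` columns.")
  rec <- tibble::as_tibble(records)
  if (!"growth_group" %in% names(rec)) rec$growth_group <- NA_character_
  rec$growth_group <- ifelse(rec$assembly_group == "A", "none", rec$growth_group)

  missing_gg <- rec$assembly_group %in% c("B", "C") &
    (is.na(rec$growth_group) | !rec$growth_group %in% c("G1", "G2", "G3"))
  abort_if(any(missing_gg),
           paste0("Growth group required for assembly groups B and C; missing for: ",
                  paste(rec$species[missing_gg], collapse = ", ")))

  out <- rec |>
    dplyr::select("species", "assembly_group", "growth_group") |>
    dplyr::left_join(defaults, by = c("assembly_group", "growth_group"))
  abort_if(anyNA(out$inoculum),
           paste0("No default inoculum for: ",
                  paste(unique(out$species[is.na(out$inoculum)]), collapse = ", ")))
  if (!is.null(overrides)) {
    hit <- match(out$species, names(overrides))
    out$inoculum <- ifelse(is.na(hit), out$inoculum, overrides[hit])
  }
  totals <- out |>
    dplyr::group_by(.data$assembly_group) |>
    dplyr::summarise(total = sum(.data$inoculum), .groups = "drop")
  structure(list(records = out, group_totals = totals,
                 schedule = build_schedule(durations)),
            class = "inoculum_plan")
}

#' @export
print.inoculum_plan <- function(x, ...) {
  cat(sprintf("<inoculum_plan> %d species in %d assembly groups\n",
              nrow(x$records), nrow(x$group_totals)))
  if (nrow(x$group_totals)) {
    for (i in seq_len(nrow(x$group_totals))) {
      cat(sprintf("  group %s: %s cells/mL\n", x$group_totals$assembly_group[i],
                  format(x$group_totals$total[i], big.mark = ",")))
    }
  }
  cat(sprintf("  schedule span: %d days\n", attr(x$schedule, "total_span")))
  invisible(x)
}

#' Sequential colonization schedule
#'
#' Cumulative start days for ordered inoculation waves: each group starts
#' when the previous group's colonization ends, and the total span is the
#' sum of the durations. The default three-wave design (A 4 d, B 14 d,
#' C 12 d) gives starts at days 0, 4 and 18 and a 30-day establishment.
#'
#' @param durations Named (or ordered) positive numeric vector of
#'   colonization durations in days.
#' @return A tibble with columns `group`, `start_day`,
#'   `colonization_days`; the total span is in `attr(, "total_span")`.
#' @examples
#' build_schedule(c(A = 4, B = 14, C = 12))
#' @export
build_schedule <- function(durations = c(A = 4, B = 14, C = 12)) {
  abort_if(length(durations) == 0L || any(!is.finite(durations)) ||
             any(durations <= 0),
           "All colonization durations must be positive.")
  groups <- names(durations) %||% paste0("group_", seq_along(durations))
  if (is.null(names(durations))) names(durations) <- groups
  sched <- tibble::tibble(
    group = groups,
    start_day = cumsum(c(0, unname(durations[-length(durations)]))),
    colonization_days = unname(durations)
  )
  attr(sched, "total_span") <- sum(unname(durations))
  sched
}
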