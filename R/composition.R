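# Count-table arithmetic: rarefaction, relative abundance, succession
# tracking across assembly time points.

#' Rarefy a count table to equal depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) to exactly `depth` reads, equalising sequencing effort
#' across samples before composition summaries. Samples with fewer than
#' `depth` reads are dropped with a warning (`policy = "drop"`) or raise
#' (`policy = "error"`). The subsampling engine is \code{vegan::rrarefy}.
#'
#' @param table Count table: data frame with a `taxon` column and one
#'   integer column per sample (see [generate_count_table()]).
#' @param depth Target reads per sample (positive integer).
#' @param seed Integer seed for reproducible subsampling.
#' @param policy How to treat samples shallower than `depth`.
#' @return The rarefied count table (same layout; possibly fewer samples).
#'   Every retained sample column sums to exactly `depth`.
#' @examples
#' tab <- generate_count_table(c(0.6, 0.4), depths = c(500, 800), seed = 1)
#' rarefy(tab, depth = 400, seed = 1)
#' @export
rarefy <- function(table, depth, seed = NULL, policy = c("drop", "error")) {
  policy <- match.arg(policy)
  abort_if(length(depth) != 1L || depth < 1, "`depth` must be a positive integer.")
  m <- count_matrix(table)
  totals <- colSums(m)
  shallow <- totals < depth
  if (any(shallow)) {
    msg <- paste0("Samples shallower than depth ", depth, ": ",
                  paste(colnames(m)[shallow], collapse = ", "))
    abort_if(policy == "error", msg)
    rlang::warn(paste0(msg, " (dropped)"))
    m <- m[, !shallow, drop = FALSE]
  }
  abort_if(ncol(m) == 0L, "No sample is deep enough to rarefy.")
  rar <- with_seed_or_not(seed, {
    # vegan warns when counts look unusually large/even; spurious here
    withCallingHandlers(
      t(vegan::rrarefy(t(m), sample = depth)),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  })
  dplyr::bind_cols(tibble::tibble(taxon = rownames(m)),
                   tibble::as_tibble(rar))
}

#' Relative abundance profiles
#'
#' Converts counts to per-sample proportions; optionally averages the
#' proportions over replicates within metadata groups (e.g. time point x
#' temperature x herbicide level), the form in which community composition
#' profiles are usually displayed.
#'
#' @param table Count table (see [rarefy()]).
#' @param metadata Optional per-sample metadata: data frame with a `sample`
#'   column matching the table's sample columns.
#' @param by Character vector of metadata columns to average over; requires
#'   `metadata`.
#' @return Without `by`: the proportion table (same layout, columns sum to
#'   1). With `by`: a long tibble of mean proportions per taxon and group,
#'   with replicate count `n`.
#' @export
relative_abundance <- function(table, metadata = NULL, by = NULL) {
  m <- count_matrix(table)
  totals <- colSums(m)
  abort_if(any(totals == 0),
           paste0("All-zero sample(s): ",
                  paste(colnames(m)[totals == 0], collapse = ", ")))
  p <- sweep(m, 2L, totals, "/")
  props <- dplyr::bind_cols(tibble::tibble(taxon = rownames(m)),
                            tibble::as_tibble(p))
  if (is.null(by)) return(props)
  abort_if(is.null(metadata) || !"sample" %in% names(metadata),
           "`by` needs `metadata` with a `sample` column.")
  abort_if(!all(by %in% names(metadata)),
           "All `by` columns must exist in `metadata`.")
  abort_if(!all(colnames(m) %in% metadata$sample),
           "Every sample column must appear in `metadata$sample`.")
  props |>
    tidyr::pivot_longer(-"taxon", names_to = "sample", values_to = "proportion") |>
    dplyr::left_join(metadata[c("sample", by)], by = "sample") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("taxon", by)))) |>
    dplyr::summarise(mean_proportion = mean(.data$proportion),
                     n = dplyr::n(), .groups = "drop")
}

#' Track species detection and loss across succession time points
#'
#' Given count tables for successive time points and the roster of
#' inoculated species, reports which roster members are detected at each
#' time point (count, or proportion, at or above `detection_threshold` in at
#' least one replicate sample) and which are lost — roster species no
#' longer detected at the final time point. Roster names missing from a
#' table's taxon namespace are reported as mismatches (and count as
#' undetected), never silently dropped.
#'
#' @param tables Named list of count tables in chronological order, e.g.
#'   `list(t1 = ..., t2 = ..., t3 = ...)`.
#' @param roster Character vector of inoculated species/taxon names.
#' @param detection_threshold Minimum count (default 1 read) — or minimum
#'   proportion when `proportion = TRUE` — required in at least one
#'   replicate for detection.
#' @param proportion Interpret the threshold on the per-sample proportion
#'   scale instead of raw counts.
#' @return A `succession_summary`: list with `detected` (named list of
#'   detected roster subsets per time point), `detected_counts` (tibble:
#'   time_point, n_detected), `lost_taxa` (undetected at the final time
#'   point), and `name_mismatches` (per time point).
#' @examples
#' t1 <- generate_count_table(c(0.5, 0.5, 0), depths = 100,
#'                            taxa = c("a", "b", "c"), seed = 1)
#' t3 <- generate_count_table(c(0.2, 0.3, 0.5), depths = 100,
#'                            taxa = c("a", "b", "c"), seed = 2)
#' track_succession(list(t1 = t1, t3 = t3), roster = c("a", "b", "c"))
#' @export
track_succession <- function(tables, roster, detection_threshold = 1,
                             proportion = FALSE) {
  abort_if(!is.list(tables) || length(tables) == 0L,
           "`tables` must be a non-empty list of count tables.")
  abort_if(length(roster) == 0L, "`roster` must name at least one taxon.")
  if (is.null(names(tables))) names(tables) <- paste0("t", seq_along(tables))
  mism <- list()
  detected <- purrr::imap(tables, function(tab, tp) {
    m <- count_matrix(tab)
    missing <- setdiff(roster, rownames(m))
    if (length(missing) > 0L) {
      mism[[tp]] <<- missing
      rlang::warn(sprintf("Time point %s: %d roster taxa absent from the table: %s",
                          tp, length(missing), paste(missing, collapse = ", ")))
    }
    if (proportion) m <- sweep(m, 2L, pmax(colSums(m), 1), "/")
    present <- rownames(m)[apply(m >= detection_threshold, 1L, any)]
    intersect(roster, union(present, if (detection_threshold <= 0) roster else character(0)))
  })
  final <- detected[[length(detected)]]
  structure(
    list(detected = detected,
         detected_counts = tibble::tibble(
           time_point = names(detected),
           n_detected = unname(lengths(detected))),
         lost_taxa = setdiff(roster, final),
         roster = roster,
         name_mismatches = mism),
    class = "succession_summary"
  )
}

#' @export
print.succession_summary <- function(x, ...) {
  cat("<succession_summary>\n")
  for (i in seq_along(x$detected)) {
    cat(sprintf("  %s: %d / %d roster taxa detected\n",
                names(x$detected)[i], length(x$detected[[i]]), length(x$roster)))
  }
  cat(sprintf("  lost at final time point: %s\n",
              if (length(x$lost_taxa)) paste(x$lost_taxa, collapse = ", ") else "none"))
  invisible(x)
}
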