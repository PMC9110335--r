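# Focal-record tables use one semicolon-separated id-list column per buffer
# (widest buffer first, then "touch"); columns are normalized to nested sets
# on read: every id in a narrower buffer also belongs to all wider ones.

split_ids <- function(x) {
  lapply(strsplit(ifelse(is.na(x) | x == "", "", x), ";", fixed = TRUE),
         function(z) z[nzchar(z)])
}

join_ids <- function(sets) {
  vapply(sets, paste, character(1), collapse = ";")
}

#' Normalize neighbour columns to nested buffer sets
#'
#' Proximity buffers are cumulative: an animal touching the focal is also
#' within 1 m, 2.5 m and 5 m. Raw input violating nesting is repaired by
#' union-closure from the narrowest buffer upward, with a warning.
#'
#' @param records Focal-record data frame.
#' @param buffer_cols Buffer columns, widest first (default: all of
#'   `n*`/`touch` present, in table order).
#' @return The records with nested neighbour columns.
#' @export
normalize_neighbours <- function(records, buffer_cols = NULL) {
  if (is.null(buffer_cols)) buffer_cols <- detect_buffer_cols(records)
  sets <- lapply(records[buffer_cols], split_ids)
  fixed <- FALSE
  # narrowest is last; push members upward into wider buffers
  for (k in rev(seq_along(buffer_cols))[-1]) {
    wider <- sets[[k]]
    narrower <- sets[[k + 1L]]
    for (i in seq_along(wider)) {
      if (!all(narrower[[i]] %in% wider[[i]])) {
        wider[[i]] <- union(wider[[i]], narrower[[i]])
        fixed <- TRUE
      }
    }
    sets[[k]] <- wider
  }
  if (fixed) warning("neighbour sets were not nested; repaired by union-closure")
  for (k in seq_along(buffer_cols)) {
    records[[buffer_cols[k]]] <- join_ids(sets[[k]])
  }
  records
}

# all individuals seen anywhere: as focal or inside any neighbour set
id_universe <- function(records) {
  nb <- unlist(lapply(records[detect_buffer_cols(records)], split_ids),
               use.names = FALSE)
  sort(unique(c(records$focal_id, nb)))
}

detect_buffer_cols <- function(records) {
  nm <- names(records)
  cols <- nm[grepl("^n[0-9]", nm) | nm == "touch"]
  if (!length(cols)) stop("no buffer columns (n*, touch) found")
  cols
}

#' Split focal records into close/far observer-distance strata
#'
#' @param records Focal-record data frame with `end_observer_distance_m`.
#' @param threshold Split distance in metres; records at distances less than
#'   or equal to the threshold are `close`, the rest `far`. Default is the
#'   median end observer distance, computed per year
#'   (`threshold_mode = "per-year-median"`) or pooled over all records
#'   (`"pooled-median"`, the convention used when one median is quoted for
#'   both years).
#' @param threshold_mode How to resolve a `NULL` threshold.
#' @return The records with a `stratum` factor column (`close`/`far`); the
#'   threshold(s) used are attached as attribute `threshold`.
#' @export
split_by_distance <- function(records, threshold = NULL,
                              threshold_mode = c("pooled-median",
                                                 "per-year-median")) {
  if (!nrow(records)) stop("empty focal table")
  threshold_mode <- match.arg(threshold_mode)
  d <- records$end_observer_distance_m
  if (is.null(threshold)) {
    if (threshold_mode == "pooled-median") {
      thr <- stats::median(d)
      records$stratum <- ifelse(d <= thr, "close", "far")
    } else {
      thr <- tapply(d, records$year, stats::median)
      records$stratum <- ifelse(d <= thr[as.character(records$year)],
                                "close", "far")
    }
  } else {
    if (threshold <= 0) stop("threshold must be positive")
    thr <- threshold
    records$stratum <- ifelse(d <= thr, "close", "far")
  }
  records$stratum <- factor(records$stratum, levels = c("far", "close"))
  attr(records, "threshold") <- thr
  records
}

#' Down-sample focals to an even number per individual per year
#'
#' @param records Focal records.
#' @param n_per_individual Named vector: year label -> retained focal count.
#' @param seed Integer seed making the random selection reproducible.
#' @return The retained records (original order preserved).
#' @export
downsample_focals <- function(records, n_per_individual, seed = 1L) {
  set.seed(seed)
  keep <- logical(nrow(records))
  for (yr in names(n_per_individual)) {
    n_keep <- n_per_individual[[yr]]
    in_year <- which(as.character(records$year) == yr)
    for (id in unique(records$focal_id[in_year])) {
      rows <- in_year[records$focal_id[in_year] == id]
      if (length(rows) < n_keep) {
        stop("individual ", id, " has only ", length(rows),
             " focals in ", yr, " (need ", n_keep, ")")
      }
      keep[sample(rows, n_keep)] <- TRUE
    }
  }
  # years absent from the plan are dropped entirely
  records[keep, , drop = FALSE]
}

#' Drop excluded individuals from a study
#'
#' Removes their focal observations and strips them from every neighbour
#' set, emulating the removal of individuals who disappeared mid-study.
#'
#' @param records Focal records.
#' @param exclude Character vector of individual ids.
#' @return Filtered records.
#' @export
exclude_individuals <- function(records, exclude) {
  if (!length(exclude)) return(records)
  records <- records[!records$focal_id %in% exclude, , drop = FALSE]
  for (col in detect_buffer_cols(records)) {
    records[[col]] <- join_ids(lapply(split_ids(records[[col]]),
                                      setdiff, y = exclude))
  }
  records
}

#' Count per-individual occurrences as a neighbour, with exposures
#'
#' For one (buffer, stratum, year) cell, each individual's count is the
#' number of focal records of the *other* group members in that cell whose
#' buffer neighbour set contains it; its exposure is the number of focal
#' samples of the other n-1 individuals in the cell, i.e. (total focals in
#' the cell) - (its own focals in the cell). The log of the exposure enters
#' the occurrence model as an offset.
#'
#' @param records Stratified focal records ([split_by_distance()]).
#' @param buffer Buffer column label (e.g. `"n5"`, `"touch"`).
#' @param stratum `"close"` or `"far"`.
#' @param year Year label.
#' @param ids Id universe (default: every individual appearing in `records`
#'   as a focal or as a neighbour).
#' @return Data frame `individual_id, year, buffer, stratum, count, exposure`
#'   with one row per individual, zeros included.
#' @export
count_occurrences <- function(records, buffer, stratum, year, ids = NULL) {
  if (!buffer %in% names(records)) stop("unknown buffer label: ", buffer)
  if (is.null(ids)) ids <- id_universe(records)
  cell <- records[records$stratum == stratum &
                    as.character(records$year) == as.character(year), ,
                  drop = FALSE]
  total <- nrow(cell)
  own <- table(factor(cell$focal_id, levels = ids))
  sets <- split_ids(cell[[buffer]])
  hits <- table(factor(unlist(sets), levels = ids))
  data.frame(individual_id = ids, year = as.character(year),
             buffer = buffer, stratum = stratum,
             count = as.integer(hits),
             exposure = as.integer(total - own),
             stringsAsFactors = FALSE)
}

#' Occurrence counts for every (individual x buffer x stratum x year) cell
#'
#' @param records Stratified focal records.
#' @param buffers Buffer labels (default: all present).
#' @param ids Id universe.
#' @return Row-bound [count_occurrences()] tables over all cells.
#' @export
count_all_occurrences <- function(records, buffers = NULL, ids = NULL) {
  if (is.null(buffers)) buffers <- detect_buffer_cols(records)
  if (is.null(ids)) ids <- id_universe(records)
  cells <- expand.grid(buffer = buffers,
                       stratum = c("close", "far"),
                       year = unique(as.character(records$year)),
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    count_occurrences(records, cells$buffer[i], cells$stratum[i],
                      cells$year[i], ids = ids)
  }))
  rownames(out) <- NULL
  out
}

#' Read / write focal-record CSV
#'
#' Canonical schema: `focal_id, year, time_period, end_observer_distance_m`,
#' then one semicolon-separated id-list column per buffer (empty allowed).
#' Neighbour sets are normalized to nested form on read.
#'
#' @param path CSV path.
#' @return Focal-record data frame.
#' @export
read_focal_csv <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(year = "character"))
  for (col in detect_buffer_cols(rec)) {
    rec[[col]][is.na(rec[[col]])] <- ""
  }
  normalize_neighbours(rec)
}

#' @rdname read_focal_csv
#' @param records Focal-record data frame.
#' @export
write_focal_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
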