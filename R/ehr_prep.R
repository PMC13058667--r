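# Ingestion: collapse raw diagnosis codes into primary diagnosis clusters
# (lifetime, date-agnostic), then apply the cohort filter (>= 1 diagnosis).

#' Collapse raw-code events into a binary diagnosis matrix
#'
#' A person is scored 1 for a diagnosis cluster iff at least one of their
#' events maps to it; event dates are ignored (lifetime operationalization).
#' Codes absent from the cluster map are counted and reported, never silently
#' dropped. The result is idempotent under event duplication.
#'
#' @param events Tibble with columns `person_id`, `raw_code` (and optionally
#'   `event_date`, unused).
#' @param map Cluster map tibble with columns `raw_code`, `diagnosis_label`,
#'   `diagnosis_index` (0-based, contiguous). Duplicate `raw_code` entries are
#'   an error.
#' @return A tibble with `person_id` (persons in order of first appearance)
#'   plus one 0/1 column per diagnosis, columns ordered by `diagnosis_index`.
#'   The full column set comes from the map, so an empty event table yields a
#'   0-row tibble with all diagnosis columns. Attribute `unmapped` holds a
#'   tibble of unmapped codes and their counts.
#' @export
collapse_codes <- function(events, map) {
  events <- tibble::as_tibble(events)
  map <- tibble::as_tibble(map)
  stopifnot(all(c("person_id", "raw_code") %in% names(events)),
            all(c("raw_code", "diagnosis_label", "diagnosis_index") %in% names(map)))
  if (anyDuplicated(map$raw_code)) {
    dup <- unique(map$raw_code[duplicated(map$raw_code)])
    stop("duplicate raw_code in cluster map: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  idx <- sort(unique(map$diagnosis_index))
  if (!identical(idx, seq_along(idx) - 1L) && length(idx))
    stop("diagnosis_index must be 0-based and contiguous", call. = FALSE)
  labels <- map$diagnosis_label[match(idx, map$diagnosis_index)]

  hit <- match(events$raw_code, map$raw_code)
  unmapped <- events$raw_code[is.na(hit)]
  unmapped_tbl <- if (length(unmapped)) {
    tb <- table(unmapped)
    tibble::tibble(raw_code = names(tb), n_events = as.integer(tb))
  } else {
    tibble::tibble(raw_code = character(0), n_events = integer(0))
  }
  if (nrow(unmapped_tbl))
    rlang::inform(paste0(sum(unmapped_tbl$n_events), " event(s) with ",
                         nrow(unmapped_tbl),
                         " unmapped raw code(s) were ignored"))
  mapped <- !is.na(hit)
  if (nrow(events) > 0 && !any(mapped))
    stop("cluster map covers no code present in the events", call. = FALSE)

  persons <- unique(events$person_id)
  m <- matrix(0, length(persons), length(labels),
              dimnames = list(NULL, labels))
  if (any(mapped)) {
    pi_ <- match(events$person_id[mapped], persons)
    di <- map$diagnosis_index[hit[mapped]] + 1L
    m[cbind(pi_, di)] <- 1
  }
  out <- tibble::tibble(person_id = as.character(persons))
  out <- dplyr::bind_cols(out, tibble::as_tibble(m))
  attr(out, "unmapped") <- unmapped_tbl
  out
}

#' Apply the cohort filter: at least one diagnosis
#'
#' Removes persons whose diagnosis row is all zero, preserving the order of
#' the remaining rows, and reports the removed count.
#'
#' @param data Binary diagnosis tibble (`person_id` + 0/1 columns).
#' @return The filtered tibble; attribute `n_removed` gives the count removed.
#' @export
filter_cohort <- function(data) {
  data <- tibble::as_tibble(data)
  m <- dx_matrix(data)
  keep <- rowSums(m) >= 1
  removed <- sum(!keep)
  if (removed)
    rlang::inform(paste0("removed ", removed,
                         " person(s) with no recorded diagnosis"))
  out <- data[keep, , drop = FALSE]
  attr(out, "n_removed") <- removed
  out
}

#' Per-diagnosis prevalence of a binary diagnosis matrix
#'
#' @param data Binary diagnosis tibble or 0/1 matrix.
#' @return A tibble with `diagnosis` and `prevalence` (exact column means).
#' @export
dx_prevalence <- function(data) {
  m <- dx_matrix(data)
  tibble::tibble(diagnosis = colnames(m),
                 prevalence = unname(colMeans(m)))
}
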