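#' Reading and writing the interchange formats
#'
#' Plain-text formats so synthetic and real inputs are interchangeable:
#' recall sequences as long CSV (one row per recalled building), building
#' coordinates as CSV (sketch and reference sources), pairwise features as
#' long CSV, and map structures as JSON-ready lists.
#'
#' @name io
NULL

#' Read recall trials from a long-format CSV
#'
#' Expected columns: `environment_id`, `sequence_index`, `cued` (0/1),
#' `cue_id`, `position`, `building_id`. The permutation property of every
#' sequence is validated on read.
#'
#' @param path CSV file path.
#' @return named list of [recall_trial()]s, one per environment.
#' @export
read_recall_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("environment_id", "sequence_index", "cued", "cue_id",
            "position", "building_id")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  out <- lapply(split(df, df$environment_id), function(d) {
    seqs <- lapply(split(d, d$sequence_index), function(s) {
      s <- s[order(s$position), ]
      cued <- s$cued[1L] == 1
      recall_sequence(s$building_id, cued = cued,
                      cue_id = if (cued) s$cue_id[1L] else NULL)
    })
    recall_trial(seqs, environment_id = d$environment_id[1L])
  })
  out
}

#' Write recall trials to the long CSV format
#'
#' @param trials list of [recall_trial()]s.
#' @param path output CSV path.
#' @export
write_recall_csv <- function(trials, path) {
  rows <- list()
  for (trial in trials) {
    for (i in seq_along(trial$sequences)) {
      s <- trial$sequences[[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        environment_id = trial$environment_id, sequence_index = i,
        cued = as.integer(s$cued),
        cue_id = ifelse(is.na(s$cue_id), "", s$cue_id),
        position = seq_along(s$ordering), building_id = s$ordering)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

#' Read building coordinates
#'
#' Columns: `environment_id`, `building_id`, `x`, `y`, `source`
#' (`"sketch"` or `"reference"`).
#'
#' @param path CSV file path.
#' @return nested list: environment -> source -> coordinate matrix.
#' @export
read_coordinates_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$environment_id), function(d)
    lapply(split(d, d$source), function(s) {
      m <- as.matrix(s[, c("x", "y")])
      rownames(m) <- s$building_id
      m
    }))
}

#' Read a long-format pairwise feature CSV
#'
#' Columns: `environment_id`, `building_a`, `building_b`, `feature_name`,
#' `value`. Completeness over all pairs and features is validated.
#'
#' @param path CSV file path.
#' @return named list of [feature_table()]s, one per environment.
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$environment_id), function(d) {
    key <- pair_key(d$building_a, d$building_b)
    wide <- stats::reshape(
      data.frame(key = key, feature = d$feature_name, value = d$value),
      idvar = "key", timevar = "feature", direction = "wide")
    vals <- as.matrix(wide[, -1L, drop = FALSE])
    colnames(vals) <- sub("^value\\.", "", colnames(vals))
    if (anyNA(vals)) stop("incomplete feature table in ", d$environment_id[1L])
    pairs <- do.call(rbind, strsplit(wide$key, "\r", fixed = TRUE))
    feature_table(pairs, vals)
  })
}

#' Map structure as a JSON-ready list
#'
#' @param structure a [map_structure()].
#' @param environment_id identifier to embed.
#' @param removed indices of jackknife-removed sequences.
#' @return list suitable for `jsonlite::write_json(..., auto_unbox = TRUE)`.
#' @export
structure_to_list <- function(structure, environment_id = "env",
                              removed = integer()) {
  list(environment_id = environment_id,
       submaps = lapply(structure$submaps, as.list),
       excluded = as.list(structure$excluded),
       singleton_clusters = lapply(structure$singleton_clusters, as.list),
       removed_sequences = as.list(removed))
}
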