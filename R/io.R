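#' Read and write parcel-indexed value tables
#'
#' Tab-separated tables keyed by a `parcel_id` column; remaining columns
#' are numeric values (one column per map or gradient). Duplicate or
#' missing parcel ids and non-numeric cells are rejected with the
#' offending line reported.
#'
#' @param path file path.
#' @return data.frame with rownames set to parcel ids.
#' @export
readParcelTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!"parcel_id" %in% colnames(tab)) {
    stop("no 'parcel_id' column in ", path)
  }
  ids <- as.character(tab$parcel_id)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate parcel id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  if (anyNA(ids) || any(ids == "")) stop("missing parcel id in ", path)
  vals <- tab[, setdiff(colnames(tab), "parcel_id"), drop = FALSE]
  for (cn in colnames(vals)) {
    v <- suppressWarnings(as.numeric(vals[[cn]]))
    bad <- which(is.na(v) & !is.na(vals[[cn]]))
    if (length(bad)) {
      stop("non-numeric cell in column '", cn, "' at data line ",
           bad[1], " of ", path)
    }
    vals[[cn]] <- v
  }
  rownames(vals) <- ids
  vals
}

#' @rdname readParcelTable
#' @param values matrix or data.frame with parcel ids as rownames.
#' @export
writeParcelTable <- function(values, path) {
  df <- data.frame(parcel_id = rownames(as.matrix(values)),
                   as.data.frame(values, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write event tables
#'
#' Tab-separated, BIDS-events-like: columns onset, duration, event_type
#' and optionally response_time.
#'
#' @param path file path.
#' @param events event table data.frame.
#' @export
writeEventTable <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' @rdname writeEventTable
#' @export
readEventTable <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "n/a")
  need <- c("onset", "duration", "event_type")
  absent <- setdiff(need, colnames(ev))
  if (length(absent)) {
    stop("event table lacks columns: ", paste(absent, collapse = ", "))
  }
  ev
}

#' Read and write probe matrices
#'
#' Comma-separated with the key columns and the 13 item columns.
#'
#' @param probes probe matrix data.frame.
#' @param path file path.
#' @export
writeProbeMatrix <- function(probes, path) {
  utils::write.csv(probes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeProbeMatrix
#' @export
readProbeMatrix <- function(path) {
  pm <- utils::read.csv(path, stringsAsFactors = FALSE)
  absent <- setdiff(mdesItemNames(), colnames(pm))
  if (length(absent)) {
    stop("probe matrix lacks item columns: ", paste(absent, collapse = ", "))
  }
  pm
}

#' Parcellate a NIfTI volume with an integer-label atlas
#'
#' Averages volume voxels within each atlas label; label 0 is background.
#' The two images must share a voxel grid.
#'
#' @param volumePath path to a 3-D NIfTI volume.
#' @param atlasPath path to an integer-labelled NIfTI atlas on the same
#'   grid.
#' @return named numeric vector of per-label means; names are
#'   `p<label>` parcel ids.
#' @export
readNiftiParcellated <- function(volumePath, atlasPath) {
  vol <- RNifti::readNifti(volumePath)
  atlas <- RNifti::readNifti(atlasPath)
  if (!identical(dim(vol), dim(atlas))) {
    stop("volume and atlas grids differ: ",
         paste(dim(vol), collapse = "x"), " vs ",
         paste(dim(atlas), collapse = "x"))
  }
  labels <- sort(unique(as.integer(atlas)))
  labels <- labels[labels != 0L]
  means <- vapply(labels, function(lb) mean(vol[atlas == lb]), numeric(1))
  stats::setNames(means, sprintf("p%04d", labels))
}

#' Write a YAML sidecar recording configuration and seed
#'
#' @param path output path (conventionally `<data>.yaml`).
#' @param config a configuration list.
#' @param seed the seed used.
#' @export
writeSidecar <- function(path, config, seed) {
  payload <- list(seed = seed,
                  config = unclass(config),
                  package = as.character(utils::packageVersion("gradientspace")),
                  configHash = configHash(config))
  yaml::write_yaml(payload, path)
  invisible(path)
}

# short deterministic hash of a configuration list (sum of character codes
# of its YAML serialisation; enough to detect accidental config drift)
configHash <- function(config) {
  txt <- yaml::as.yaml(unclass(config))
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1)))
}
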