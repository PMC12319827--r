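# Plain-text readers/writers for the package's data objects: delimited
# connectome matrices with a JSON sidecar, label/scalar volumes, streamline
# sets, and cohort tables. NIfTI volumes are supported when RNifti is
# available.

#' Write a connectome matrix with a JSON sidecar
#'
#' The matrix goes to tab-delimited text; weighting, parcellation id and size
#' go to `<path>.json`.
#'
#' @param connectome A `connectome`.
#' @param path Output file path.
#' @export
write_connectome <- function(connectome, path) {
  utils::write.table(unclass(connectome), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(weighting = attr(connectome, "weighting"),
         parcellation_id = attr(connectome, "parcellation_id"),
         n_rois = nrow(connectome)),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' Read a connectome written by [write_connectome()]
#'
#' @param path File path.
#'
#' @return A `connectome`.
#' @export
read_connectome <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(m) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  connectome(m, meta$weighting, meta$parcellation_id)
}

#' Write a 3D volume as plain text (or NIfTI)
#'
#' Plain-text format: first line holds the three dimensions, the rest the
#' values in column-major order. Paths ending in `.nii`/`.nii.gz` are written
#' as NIfTI via RNifti when installed.
#'
#' @param volume 3D array (`label_volume`, scalar volume, or `prediction_map`).
#' @param path Output file path.
#' @export
write_volume <- function(volume, path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      abort("writing NIfTI requires the RNifti package")
    }
    RNifti::writeNifti(array(as.numeric(volume), dim = dim(volume)), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(dim(volume), collapse = " "), con)
    writeLines(paste(as.vector(volume), collapse = " "), con)
  }
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path File path.
#' @param label Return an integer `label_volume`?
#'
#' @return A 3D array.
#' @export
read_volume <- function(path, label = FALSE) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      abort("reading NIfTI requires the RNifti package")
    }
    vol <- array(as.numeric(RNifti::readNifti(path)), dim = dim(RNifti::readNifti(path)))
  } else {
    lines <- readLines(path)
    d <- as.integer(strsplit(lines[1], " ")[[1]])
    vol <- array(as.numeric(strsplit(lines[2], " ")[[1]]), dim = d)
  }
  if (label) {
    storage.mode(vol) <- "integer"
    vol <- structure(vol, class = "label_volume", n_rois = max(vol))
  }
  vol
}

#' Write a streamline set as one path per line
#'
#' Each line holds the voxel coordinates of one streamline as
#' `x1,y1,z1;x2,y2,z2;...`.
#'
#' @param streamline_set A `streamline_set`.
#' @param path Output file path.
#' @export
write_streamlines <- function(streamline_set, path) {
  lines <- vapply(streamline_set, function(p) {
    paste(apply(p, 1, paste, collapse = ","), collapse = ";")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a streamline set written by [write_streamlines()]
#'
#' @param path File path.
#'
#' @return A `streamline_set`.
#' @export
read_streamlines <- function(path) {
  paths <- lapply(readLines(path), function(line) {
    do.call(rbind, lapply(strsplit(line, ";")[[1]], function(v) {
      as.integer(strsplit(v, ",")[[1]])
    }))
  })
  structure(paths, class = "streamline_set")
}

#' Write a cohort table as CSV
#'
#' Columns: subject_id, sex, the five trait totals, cognition.
#'
#' @param cohort A `cohort`.
#' @param path Output file path.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(tibble::as_tibble(as.data.frame(cohort)), path)
  invisible(path)
}

#' Read a cohort CSV
#'
#' @param path File path.
#'
#' @return A `cohort` tibble (without item-level responses).
#' @export
read_cohort <- function(path) {
  cohort <- readr::read_csv(path, show_col_types = FALSE)
  structure(cohort, class = c("cohort", class(cohort)))
}
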