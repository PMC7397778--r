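# Dataset serialization: 8-bit RGB PNG tiles, one CSV of point annotations
# (case_id,row,col,label; 0-based integer pixel coordinates) and a JSON
# manifest listing image paths.

#' Write a dataset of annotated images to a directory
#'
#' Writes each image as an 8-bit RGB PNG named after its case id, all
#' annotations into `annotations.csv` with header
#' `case_id,row,col,label`, and a `manifest.json` listing the files.
#'
#' @param images list of [AnnotatedImage-class] objects.
#' @param dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
writeDataset <- function(images, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(images, function(img) {
    file <- paste0(caseId(img), ".png")
    png::writePNG(pixels(img), file.path(dir, file))
    list(case_id = caseId(img), path = file)
  })
  ann <- do.call(rbind, lapply(images, function(img) {
    a <- annotations(img)
    if (!nrow(a)) return(NULL)
    data.frame(case_id = caseId(img), row = a$row, col = a$col,
               label = a$label, stringsAsFactors = FALSE)
  }))
  if (is.null(ann))
    ann <- data.frame(case_id = character(0), row = integer(0),
                      col = integer(0), label = character(0))
  utils::write.csv(ann, file.path(dir, "annotations.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- list(images = entries, annotations = "annotations.csv")
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a dataset written by [writeDataset()]
#'
#' @param dir directory containing `manifest.json`.
#' @return list of [AnnotatedImage-class] objects.
#' @export
readDataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  ann <- utils::read.csv(file.path(dir, manifest$annotations),
                         stringsAsFactors = FALSE)
  lapply(manifest$images, function(e) {
    pix <- png::readPNG(file.path(dir, e$path))
    a <- ann[ann$case_id == e$case_id,
             c("row", "col", "label"), drop = FALSE]
    rownames(a) <- NULL
    AnnotatedImage(pix, a, e$case_id)
  })
}

#' Write detections to CSV
#'
#' One row per detection with header `case_id,row,col,label,score`.
#' @param detections named list of detection data.frames (names are case
#'   ids), or a single data.frame with a `case_id` column.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeDetections <- function(detections, path) {
  if (is.data.frame(detections)) {
    out <- detections
  } else {
    out <- do.call(rbind, lapply(names(detections), function(cid) {
      d <- detections[[cid]]
      if (!nrow(d)) return(NULL)
      cbind(data.frame(case_id = cid, stringsAsFactors = FALSE), d)
    }))
    if (is.null(out))
      out <- data.frame(case_id = character(0), row = integer(0),
                        col = integer(0), label = character(0),
                        score = numeric(0))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a MetricsReport to JSON
#'
#' @param report a [MetricsReport-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
  stopifnot(is(report, "MetricsReport"))
  out <- list(detection = detectionMetrics(report),
              perClass = classMetrics(report),
              weighted = weightedMetrics(report),
              pixel = pixelMetrics(report),
              classCounts = as.list(report@classCounts))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}
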