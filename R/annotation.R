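#' Rasterise eating intervals into per-sample labels
#'
#' Marks a sample as eating iff its timestamp falls inside any half-open
#' interval \code{[start, stop)} after mapping the interval times from the
#' camera clock onto the watch clock (watch time = camera time − offset).
#' Half-open intervals avoid double-counting shared boundaries.
#'
#' @param intervals Data frame with columns \code{start_s}, \code{stop_s}
#'   (camera clock).
#' @param t_s Numeric sample timestamps (watch clock).
#' @param offset_s Camera-minus-watch clock offset; either a scalar or, when
#'   \code{intervals} has a \code{segment_id} column, a data frame of
#'   per-segment offsets (\code{segment_id}, \code{offset_s}).
#' @return Logical vector the length of \code{t_s}.
#' @export
rasterize_intervals <- function(intervals, t_s, offset_s = 0) {
  labels <- logical(length(t_s))
  if (!nrow(intervals)) return(labels)
  if (is.data.frame(offset_s)) {
    off <- offset_s$offset_s[match(intervals$segment_id,
                                   offset_s$segment_id)]
    off[is.na(off)] <- 0
  } else {
    off <- rep_len(offset_s, nrow(intervals))
  }
  for (i in seq_len(nrow(intervals))) {
    labels <- labels | (t_s >= intervals$start_s[i] - off[i] &
                          t_s < intervals$stop_s[i] - off[i])
  }
  labels
}

#' Fuse two evaluators' eating labels into united and intersected sets
#'
#' The united label set marks a sample as eating when at least one evaluator
#' did (element-wise OR); the intersected set requires both (element-wise
#' AND). Intersected therefore always implies united.
#'
#' @param track_a,track_b Logical label vectors of equal length, or
#'   \code{annotation_track} objects carrying \code{$labels}.
#' @return Object of class \code{fused_labels}: list with logical vectors
#'   \code{united} and \code{intersected}.
#' @examples
#' combine_labels(c(TRUE, TRUE, FALSE), c(FALSE, TRUE, FALSE))
#' @export
combine_labels <- function(track_a, track_b) {
  a <- if (inherits(track_a, "annotation_track")) track_a$labels else track_a
  b <- if (inherits(track_b, "annotation_track")) track_b$labels else track_b
  if (!is.logical(a) || !is.logical(b)) {
    stop("tracks must be logical label vectors (or annotation_track ",
         "objects with rasterised labels)")
  }
  if (length(a) != length(b)) {
    stop("label length mismatch: track A has ", length(a),
         " samples, track B has ", length(b))
  }
  structure(list(united = a | b, intersected = a & b),
            class = "fused_labels")
}

#' @export
print.fused_labels <- function(x, ...) {
  cat(sprintf("<fused_labels> %d samples: %d united, %d intersected eating\n",
              length(x$united), sum(x$united), sum(x$intersected)))
  invisible(x)
}

#' Read or write annotation intervals as JSON
#'
#' The interchange format is a JSON array of objects with fields
#' \code{segment_id}, \code{food_id}, \code{evaluator}, \code{start_s},
#' \code{stop_s}, times on the camera clock.
#'
#' @param intervals Data frame with those columns.
#' @param path File path.
#' @return \code{read_annotations} returns the data frame;
#'   \code{write_annotations} returns \code{path} invisibly.
#' @export
write_annotations <- function(intervals, path) {
  need <- c("segment_id", "food_id", "evaluator", "start_s", "stop_s")
  missing_cols <- setdiff(need, names(intervals))
  if (length(missing_cols)) {
    stop("annotation table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  jsonlite::write_json(intervals[need], path, dataframe = "rows",
                       digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(df) == 0) {
    return(data.frame(segment_id = character(), food_id = character(),
                      evaluator = character(), start_s = numeric(),
                      stop_s = numeric(), stringsAsFactors = FALSE))
  }
  as.data.frame(df, stringsAsFactors = FALSE)
}
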