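# Segments: labelled point-to-point movements on the virtual cube -------------

.gravity_levels <- c("against", "towards", "ground")
.cross_body_levels <- c("small", "large")

#' Construct a movement segment
#'
#' A segment is one source-to-target point-to-point movement together with the
#' four condition labels under which it is executed: target presentation
#' (embedded real object vs purely virtual), movement type (reach away from the
#' body vs return towards it), direction relative to gravity, and the magnitude
#' of the cross-body component.
#'
#' @param id Integer segment number (1..13 in the standard workspace).
#' @param source,target Numeric length-3 endpoints in metres. May be omitted if
#'   `length` is given (metrics depend only on relative geometry).
#' @param length Segment length in metres. When both endpoints are supplied it
#'   must equal the Euclidean source-target distance to within `1e-9`.
#' @param embedded Logical; `TRUE` if the target has an embedded (real-world)
#'   object aiding depth perception.
#' @param reach Logical; `TRUE` for reaching (away from the body) movements,
#'   `FALSE` for returning.
#' @param gravity One of `"against"`, `"towards"`, `"ground"`.
#' @param cross_body One of `"small"`, `"large"`.
#' @param default_duration Default execution duration in seconds (> 0).
#' @return An object of class `reachadapt_segment`.
#' @examples
#' segment(1, source = c(0, 0, 0), target = c(0.35, 0, 0),
#'         embedded = TRUE, reach = TRUE, gravity = "ground",
#'         cross_body = "large")
#' @export
segment <- function(id, source = NULL, target = NULL, length = NULL,
                    embedded, reach, gravity, cross_body,
                    default_duration = 4) {
  id <- as.integer(id)
  stopifnot(length(id) == 1L, !is.na(id))
  gravity <- match.arg(gravity, .gravity_levels)
  cross_body <- match.arg(cross_body, .cross_body_levels)
  stopifnot(is.logical(embedded), length(embedded) == 1L,
            is.logical(reach), length(reach) == 1L,
            is.numeric(default_duration), default_duration > 0)
  if (!is.null(source)) source <- as_point3(source)
  if (!is.null(target)) target <- as_point3(target)
  if (!is.null(source) && !is.null(target)) {
    d <- sqrt(sum((target - source)^2))
    if (is.null(length)) {
      length <- d
    } else if (abs(length - d) > 1e-9) {
      stop(sprintf(
        "declared length %.6f m disagrees with endpoint distance %.6f m",
        length, d), call. = FALSE)
    }
  }
  if (is.null(length) || !is.numeric(length) || length <= 0) {
    stop("segment needs a positive length (or both endpoints)", call. = FALSE)
  }
  structure(
    list(id = id, source = source, target = target, length = length,
         embedded = embedded, reach = reach, gravity = gravity,
         cross_body = cross_body, default_duration = default_duration),
    class = "reachadapt_segment"
  )
}

#' @export
print.reachadapt_segment <- function(x, ...) {
  cat(sprintf(
    "<segment %d> %.3f m | %s | %s | %s gravity | %s cross-body | default %.2g s\n",
    x$id, x$length,
    if (x$embedded) "embedded" else "virtual",
    if (x$reach) "reach" else "return",
    x$gravity, x$cross_body, x$default_duration))
  invisible(x)
}

# unit direction for endpoint synthesis, chosen so that "against"/"towards"
# segments have a genuine vertical component and "large" cross-body segments a
# genuine lateral (y) component
.segment_direction <- function(gravity, cross_body) {
  zsign <- switch(gravity, against = 1, towards = -1, ground = 0)
  if (gravity == "ground") {
    if (cross_body == "small") c(1, 0, 0) else c(0.6, 0.8, 0)
  } else {
    if (cross_body == "small") c(0.6, 0, 0.8 * zsign) else c(0.48, 0.64, 0.6 * zsign)
  }
}

#' The standard 13-segment virtual-cube workspace
#'
#' Builds the thirteen segments of the experimental workspace from the packaged
#' segment table (lengths and the four condition labels). Published lengths and
#' labels are authoritative; absolute endpoint coordinates were not published,
#' so endpoints are synthesised consistently with the lengths and labels
#' (vertical component for against/towards-gravity segments, lateral component
#' for large cross-body segments). Every performance metric in this package
#' depends only on source, target and length, not on absolute placement.
#'
#' @param default_duration Default duration per segment in seconds.
#' @return A list of 13 [segment()] objects, named `seg1` .. `seg13`.
#' @examples
#' segs <- cube_segments()
#' segs[[6]]
#' @export
cube_segments <- function(default_duration = 4) {
  tab <- load_fixture("segments")
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    dir <- .segment_direction(tab$gravity[i], tab$cross_body[i])
    src <- c(-0.2 + 0.02 * i, 0.35, 0.25)
    tgt <- src + tab$length_m[i] * dir
    out[[i]] <- segment(
      id = tab$id[i], source = src, target = tgt, length = tab$length_m[i],
      embedded = tab$embedded[i], reach = tab$reach[i],
      gravity = tab$gravity[i], cross_body = tab$cross_body[i],
      default_duration = default_duration
    )
  }
  names(out) <- paste0("seg", tab$id)
  out
}
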