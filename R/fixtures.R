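# Packaged table transcriptions and demographics utilities ---------------------

# content pins for the packaged transcriptions; a mismatch means the packaged
# data were edited and can no longer be trusted as a faithful transcription
.fixture_files <- c(
  participants = "participants.csv",
  table3_durations = "table3_durations.csv",
  segments = "segments.csv",
  coding_reference = "coding_reference.csv",
  model2_coefficients = "model2_coefficients.csv"
)

.fixture_md5 <- c(
  participants = "f15bc2d729431b8a51b0db4681328d3f",
  table3_durations = "468e8915547dd19b92c8631a2ff5221d",
  segments = "128e95cba53f87dd0159f5a9e094a005",
  coding_reference = "455052c1cd71a8d8ebd26cb1068bac5e",
  model2_coefficients = "49236193f521ca97936126c9d76ab735"
)

#' Load a packaged data fixture
#'
#' The package ships plain-CSV transcriptions of the published study tables:
#' `participants` (cohort demographics), `table3_durations` (the worked
#' example participant's per-segment durations across the assisted
#' repetitions), `segments` (the 13 segment lengths and condition labels),
#' `coding_reference` (dummy-variable categories and reference levels) and
#' `model2_coefficients` (the published interaction-model regression
#' coefficients). Files are checksum-pinned; loading fails if a transcription
#' has been altered.
#'
#' @param name Fixture name: `"participants"`, `"table3_durations"`,
#'   `"segments"`, `"coding_reference"` or `"model2_coefficients"`.
#' @param check Verify the file checksum (default `TRUE`).
#' @return A tibble of validated records.
#' @examples
#' load_fixture("segments")
#' @export
load_fixture <- function(name, check = TRUE) {
  if (!name %in% names(.fixture_files)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(.fixture_files), collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", .fixture_files[[name]],
                      package = "reachadapt", mustWork = TRUE)
  if (check) {
    got <- unname(tools::md5sum(path))
    if (!identical(got, unname(.fixture_md5[[name]]))) {
      stop("fixture '", name, "' failed its checksum: packaged transcription ",
           "has been modified", call. = FALSE)
    }
  }
  df <- tibble::as_tibble(utils::read.csv(path))
  switch(
    name,
    participants = {
      stopifnot(!anyDuplicated(df$id), all(df$age > 0))
      df
    },
    segments = {
      stopifnot(nrow(df) == 13L, all(df$length_m > 0),
                all(df$gravity %in% .gravity_levels),
                all(df$cross_body %in% .cross_body_levels))
      df$id <- as.integer(df$id)
      df
    },
    table3_durations = {
      stopifnot(all(df$duration_s > 0), all(df$mode %in% c("AA1", "AA2")))
      df
    },
    model2_coefficients = {
      stopifnot(sum(df$symbol == "Constant") == 1L)
      df
    },
    df
  )
}

#' Published per-segment duration sequences as numeric vectors
#'
#' Convenience accessor over the `table3_durations` fixture: the adaptive-mode
#' (AA2) duration sequence of every segment, in iteration order, for one
#' participant.
#'
#' @param participant Participant id present in the fixture (default 2, the
#'   published worked example).
#' @return Named list of numeric vectors, `seg1` .. `seg13`.
#' @export
aa2_duration_sequences <- function(participant = 2) {
  tab <- load_fixture("table3_durations")
  tab <- tab[tab$participant == participant & tab$mode == "AA2", ]
  if (nrow(tab) == 0) stop("no AA2 records for participant ", participant,
                           call. = FALSE)
  segs <- sort(unique(tab$seg))
  out <- lapply(segs, function(s) {
    sub <- tab[tab$seg == s, ]
    sub$duration_s[order(sub$iteration)]
  })
  names(out) <- paste0("seg", segs)
  out
}

#' Cohort demographic summary
#'
#' Sample size after exclusions and the age distribution of the recruited
#' cohort. The age summary always describes all recruited participants (the
#' published convention); exclusions affect only `n_included`.
#'
#' @param records Participant records, as from `load_fixture("participants")`.
#' @param exclusions Integer ids excluded from analysis.
#' @param sd_type `"population"` (divisor n, the reporting default) or
#'   `"sample"` (divisor n - 1).
#' @param digits Rounding for the reported mean/SD (default 1).
#' @return List with `n_included`, `mean_age`, `sd_age`.
#' @examples
#' cohort_summary(load_fixture("participants"), exclusions = c(28, 29))
#' @export
cohort_summary <- function(records, exclusions = integer(),
                           sd_type = c("population", "sample"), digits = 1) {
  sd_type <- match.arg(sd_type)
  stopifnot(all(c("id", "age") %in% names(records)))
  unknown <- setdiff(exclusions, records$id)
  if (length(unknown) > 0) {
    stop("unknown exclusion id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  age <- records$age
  s <- stats::sd(age)
  if (sd_type == "population") s <- s * sqrt((length(age) - 1) / length(age))
  list(
    n_included = sum(!records$id %in% exclusions),
    mean_age = round(mean(age), digits),
    sd_age = round(s, digits)
  )
}
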