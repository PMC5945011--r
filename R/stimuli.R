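#' Read a stimulus table
#'
#' Reads a tab-separated stimulus file with columns `picture`, `category`,
#' `onset`, `related_distractor` and `unrelated_distractor` (UTF-8, header
#' required). Each row describes one target picture: its semantic category,
#' the first phoneme of its name, a distractor word from the same category
#' and a distractor word from a different category.
#'
#' @param path Path to the TSV file. Defaults to the synthetic 40-item set
#'   shipped with the package, which mirrors the structure of a published
#'   picture-word interference stimulus list (e.g. target "been"/leg with
#'   related distractor "arm" and unrelated distractor "tafel"/table).
#' @return A data.frame of class `stimulus_set`, one row per picture.
#' @export
#' @examples
#' stim <- read_stimuli()
#' head(stim)
read_stimuli <- function(path = system.file("extdata", "stimuli_synthetic.tsv",
                                            package = "racestop")) {
  stim <- utils::read.delim(path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  needed <- c("picture", "category", "onset",
              "related_distractor", "unrelated_distractor")
  missing <- setdiff(needed, names(stim))
  if (length(missing))
    stop("stimulus file lacks column(s): ", paste(missing, collapse = ", "))
  stim <- stim[, needed]
  validate_stimuli(stim)
  class(stim) <- c("stimulus_set", "data.frame")
  stim
}

#' Validate stimulus-set invariants
#'
#' Checks that picture names are unique, that no picture equals either of its
#' distractors, that the related distractor shares the picture's semantic
#' category wherever the distractor also occurs as a picture, and that the
#' unrelated distractor never shares it.
#'
#' @param stim A stimulus data.frame as returned by [read_stimuli()].
#' @return The input, invisibly; errors on violation.
#' @export
validate_stimuli <- function(stim) {
  if (anyDuplicated(stim$picture))
    stop("duplicate picture names in stimulus set")
  if (any(stim$picture == stim$related_distractor) ||
      any(stim$picture == stim$unrelated_distractor))
    stop("a picture is paired with itself as distractor")
  if (any(stim$related_distractor == stim$unrelated_distractor))
    stop("related and unrelated distractor identical for some picture")
  # category checks are only decidable for distractors that are themselves
  # pictures; distractor words outside the picture set carry no category here
  idx <- match(stim$unrelated_distractor, stim$picture)
  bad <- which(!is.na(idx) & stim$category[idx] == stim$category)
  if (length(bad))
    stop("unrelated distractor from same category for picture(s): ",
         paste(stim$picture[bad], collapse = ", "))
  invisible(stim)
}
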