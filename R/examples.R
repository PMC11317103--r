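#' Paths to bundled example data
#'
#' The package ships three small plain-text illustrations used throughout
#' the documentation and tests: a worked-example table of per-category
#' hygiene review counts and sub-aspect tallies
#' (`worked_example_assessments.csv`), an eight-month review series for
#' one casual-dining restaurant (`monthly_series_example.csv`), and a pair
#' of independently written reviews used to illustrate the
#' pattern-recognition metrics (`review_pair_example.csv`).
#'
#' @param file File name; with no argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
#' @examples
#' foodsig_example()
#' read.csv(foodsig_example("worked_example_assessments.csv"))
foodsig_example <- function(file = NULL) {
  dir <- system.file("extdata", package = "foodsig", mustWork = TRUE)
  if (is.null(file)) {
    return(list.files(dir, pattern = "\\.csv$"))
  }
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("no bundled example file called ", file)
  path
}
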