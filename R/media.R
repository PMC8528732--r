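## Media loading, writing and supplementation operators.

#' Load a growth medium from TSV
#'
#' The file must have exactly the header
#' \code{metabolite_id\tconcentration_mM\treplenished}.  Duplicate
#' metabolite rows are an error (never a silent sum), as are negative
#' concentrations and unknown columns.
#'
#' @param path TSV file.
#' @param name medium name; defaults to the file name without extension.
#' @return a [Medium-class].
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeMedium(makeMediaSuite()$rich, tsv)
#' loadMedium(tsv)
#' @export
loadMedium <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("medium file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  want <- c("metabolite_id", "concentration_mM", "replenished")
  extra <- setdiff(names(df), want)
  if (length(extra))
    stop("unknown column(s) in medium file: ", paste(extra, collapse = ", "))
  miss <- setdiff(want, names(df))
  if (length(miss))
    stop("medium file lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$metabolite_id))
    stop("duplicate metabolite row(s): ",
         paste(unique(df$metabolite_id[duplicated(df$metabolite_id)]),
               collapse = ", "))
  conc <- as.numeric(df$concentration_mM)
  if (any(is.na(conc))) stop("non-numeric concentration in medium file")
  if (any(conc < 0)) stop("negative concentration in medium file")
  repl <- tolower(as.character(df$replenished)) %in% c("true", "t", "1", "yes")
  Medium(name, setNames(conc, df$metabolite_id), df$metabolite_id[repl])
}

#' Write a medium to TSV
#'
#' Inverse of [loadMedium()] up to row order and float formatting.
#'
#' @param medium a [Medium-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeMedium <- function(medium, path) {
  df <- data.frame(metabolite_id = names(medium@components),
                   concentration_mM = unname(medium@components),
                   replenished = names(medium@components) %in%
                     medium@replenished)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Supplement a medium with one metabolite
#'
#' Returns a copy of the medium with the metabolite's concentration
#' \emph{increased} by \code{mM} (added as a new component when absent);
#' the original is unchanged and the copy's name is suffixed
#' \code{"+<metabolite>@<mM>"}.  Supplementation is additive and commutes
#' across distinct metabolites.
#'
#' @param medium a [Medium-class].
#' @param metaboliteId metabolite to add.
#' @param mM dose in mM (>= 0).
#' @return a new [Medium-class].
#' @examples
#' hd <- makeMediaSuite()$limiting
#' supplementMedium(hd, "cpd_M", 10)
#' @export
supplementMedium <- function(medium, metaboliteId, mM) {
  stopifnot(length(metaboliteId) == 1L, mM >= 0)
  comp <- medium@components
  if (metaboliteId %in% names(comp)) {
    comp[metaboliteId] <- comp[metaboliteId] + mM
  } else {
    comp <- c(comp, setNames(mM, metaboliteId))
  }
  Medium(sprintf("%s+%s@%g", medium@name, metaboliteId, mM), comp,
         medium@replenished)
}

#' Preset supplementation dose ladder
#'
#' The five-dose ladder used for dose-response profiling:
#' 10 nM, 0.1 uM, 0.1 mM, 1 mM and 100 mM, expressed in mM.
#'
#' @return numeric vector of doses in mM.
#' @export
doseLadder <- function() c(1e-5, 1e-4, 0.1, 1, 100)
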