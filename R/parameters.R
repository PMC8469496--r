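# CPD parameter-name grammar: {MN|SD}-{V|C|MALS|UMALS|LMALS|LALS|AL2}-{cell}.
# The core grammar admits 2 x 7 x 4 = 56 canonical names; additional cell
# types can be registered at run time.

.cpd_state <- new.env(parent = emptyenv())
.cpd_state$cellTypes <- c("NE", "LY", "MO", "EO")

# literature aliases (e.g. "MNV" for mean neutrophil volume)
.cpd_aliases <- c(
  "MNV"    = "MN-V-NE",
  "MNV-SD" = "SD-V-NE",
  "MNC"    = "MN-C-NE",
  "MNC-SD" = "SD-C-NE"
)

#' CPD grammar vocabularies
#'
#' The token sets of the parameter-name grammar. `cpdCellTypes()` starts
#' from the four core leukocyte populations and reflects any additional
#' registrations.
#'
#' @return character vector of valid tokens.
#' @export
cpdStatistics <- function() c("MN", "SD")

#' @rdname cpdStatistics
#' @export
cpdChannels <- function() c("V", "C", "MALS", "UMALS", "LMALS", "LALS", "AL2")

#' @rdname cpdStatistics
#' @export
cpdCellTypes <- function() .cpd_state$cellTypes

#' Register or reset cell types
#'
#' Extends the parameter grammar with extra gated populations (for
#' example an analyser reporting early granulated cells), or restores
#' the core set NE/LY/MO/EO.
#'
#' @param code cell-type code(s) to add; canonicalised to upper case.
#' @return the updated cell-type vector, invisibly.
#' @export
registerCPDCellType <- function(code) {
  stopifnot(is.character(code), all(nzchar(code)))
  code <- toupper(trimws(code))
  if (any(grepl("-", code, fixed = TRUE)))
    stop("cell-type codes may not contain '-'")
  .cpd_state$cellTypes <- unique(c(.cpd_state$cellTypes, code))
  invisible(.cpd_state$cellTypes)
}

#' @rdname registerCPDCellType
#' @export
resetCPDCellTypes <- function() {
  .cpd_state$cellTypes <- c("NE", "LY", "MO", "EO")
  invisible(.cpd_state$cellTypes)
}

#' All canonical parameter names
#'
#' @return character vector of `{statistic}-{channel}-{cellType}` names
#'   over the current grammar (56 for the core cell types), ordered by
#'   statistic, then channel, then cell type.
#' @export
canonicalParameters <- function() {
  grid <- expand.grid(cellType = cpdCellTypes(), channel = cpdChannels(),
                      statistic = cpdStatistics(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  paste(grid$statistic, grid$channel, grid$cellType, sep = "-")
}

#' Normalise a parameter name to canonical form
#'
#' Case-insensitive; accepts underscore separators (`"SD_V_NE"`) and the
#' literature aliases `MNV`/`MNV-SD` (mean / SD of neutrophil volume).
#' Does not validate tokens -- see [parseParameter()].
#'
#' @param name character vector of parameter names.
#' @return character vector of normalised names.
#' @export
normalizeParameterName <- function(name) {
  x <- toupper(trimws(as.character(name)))
  x <- gsub("_", "-", x, fixed = TRUE)
  hit <- match(x, names(.cpd_aliases))
  x[!is.na(hit)] <- .cpd_aliases[hit[!is.na(hit)]]
  x
}

#' Parse a CPD parameter name
#'
#' @param name a single parameter name in any accepted dialect.
#' @return a [CPDParameter-class].
#' @examples
#' parseParameter("SD-V-NE")
#' parseParameter("mn_al2_ne")
#' @export
parseParameter <- function(name) {
  stopifnot(length(name) == 1L)
  x <- normalizeParameterName(name)
  parts <- strsplit(x, "-", fixed = TRUE)[[1]]
  if (length(parts) != 3L)
    stop(sprintf("malformed parameter name '%s': expected 3 '-'-separated tokens, got %d",
                 name, length(parts)))
  if (!parts[1] %in% cpdStatistics())
    stop(sprintf("malformed parameter name '%s': unknown statistic '%s'",
                 name, parts[1]))
  if (!parts[2] %in% cpdChannels())
    stop(sprintf("malformed parameter name '%s': unknown channel '%s'",
                 name, parts[2]))
  if (!parts[3] %in% cpdCellTypes())
    stop(sprintf("malformed parameter name '%s': unknown cell type '%s'",
                 name, parts[3]))
  new("CPDParameter", statistic = parts[1], channel = parts[2],
      cellType = parts[3])
}

#' Format a CPDParameter as its canonical name
#'
#' @param param a [CPDParameter-class].
#' @return canonical `{statistic}-{channel}-{cellType}` string.
#' @export
formatParameter <- function(param) {
  stopifnot(is(param, "CPDParameter"))
  paste(param@statistic, param@channel, param@cellType, sep = "-")
}

#' Test whether names are canonical CPD parameter names
#'
#' Vectorised; `FALSE` for anything [parseParameter()] would reject,
#' including non-canonical dialect spellings (normalise first).
#'
#' @param name character vector.
#' @return logical vector.
#' @export
isCanonicalParameter <- function(name) {
  if (!length(name)) return(logical(0))
  parts <- strsplit(as.character(name), "-", fixed = TRUE)
  vapply(parts, function(p) {
    length(p) == 3L && p[1] %in% cpdStatistics() &&
      p[2] %in% cpdChannels() && p[3] %in% cpdCellTypes()
  }, logical(1))
}

setMethod("show", "CPDParameter", function(object) {
  stat <- c(MN = "mean", SD = "standard deviation")[object@statistic]
  cat(sprintf("CPDParameter %s (%s of channel %s over %s)\n",
              formatParameter(object), stat, object@channel,
              object@cellType))
})
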