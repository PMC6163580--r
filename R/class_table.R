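#' Read a bead hydropathy/radius class table
#'
#' The class table maps residue names (three-letter codes, one-letter codes,
#' or arbitrary tokens such as `ADA`) to a hydropathy class and a bead radius
#' in nm. Residues absent from the table fall back to the table's default
#' (class `"other"`, radius 0.26 nm in the shipped table) rather than
#' failing, so non-natural residues in input files are tolerated.
#'
#' @param path Path to a YAML file with top-level keys `default`
#'   (`class`, `radius_nm`) and `residues` (map residue name ->
#'   `{class, radius_nm}`); `radius_nm` may be omitted per residue.
#' @return An object of class `class_table`: a list with elements
#'   `default` and `residues`.
#' @seealso [default_class_table()]
#' @export
read_class_table <- function(path) {
  if (!file.exists(path)) {
    stop("class table file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$default)) raw$default <- list()
  def <- list(
    class = raw$default$class %||% "other",
    radius_nm = raw$default$radius_nm %||% 0.26
  )
  if (!def$class %in% BEAD_CLASSES) {
    stop("class table default class must be one of: ",
         paste(BEAD_CLASSES, collapse = ", "), call. = FALSE)
  }
  residues <- raw$residues %||% list()
  for (nm in names(residues)) {
    cl <- residues[[nm]]$class %||% def$class
    if (!cl %in% BEAD_CLASSES) {
      stop("unknown hydropathy class '", cl, "' for residue '", nm, "'",
           call. = FALSE)
    }
    residues[[nm]] <- list(
      class = cl,
      radius_nm = residues[[nm]]$radius_nm %||% def$radius_nm
    )
  }
  structure(list(default = def, residues = residues), class = "class_table")
}

#' Default bead class table
#'
#' The table shipped with the package: the 20 standard residues (three- and
#' one-letter codes) plus the non-natural residues ADA (long-alkyl
#' hydrophobic) and ABZ (aromatic cap, treated like PHE), and DPC. All beads
#' default to the 0.26 nm coarse-grained radius.
#'
#' @return A `class_table` object.
#' @export
default_class_table <- function() {
  path <- system.file("extdata", "bead_classes.yaml", package = "cgbeta")
  read_class_table(path)
}

#' Look up the hydropathy class and radius of a residue name
#'
#' @param table A `class_table`.
#' @param residue_name Character vector of residue names.
#' @return A data.frame with columns `class` and `radius_nm`, one row per
#'   input name; unknown names get the table default.
#' @export
lookup_residue <- function(table, residue_name) {
  stopifnot(inherits(table, "class_table"))
  cls <- character(length(residue_name))
  rad <- numeric(length(residue_name))
  for (k in seq_along(residue_name)) {
    hit <- table$residues[[residue_name[k]]]
    if (is.null(hit)) {
      cls[k] <- table$default$class
      rad[k] <- table$default$radius_nm
    } else {
      cls[k] <- hit$class
      rad[k] <- hit$radius_nm
    }
  }
  data.frame(class = cls, radius_nm = rad, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
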