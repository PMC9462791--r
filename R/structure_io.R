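#' Read alpha-carbon coordinates from a PDB file
#'
#' Extracts one CA coordinate per residue for a chain; alternate locations
#' are resolved to the highest-occupancy record.
#'
#' @param path PDB file.
#' @param chain Chain identifier.
#' @return An object of class `ca_structure`: data frame with columns
#'   `resno`, `x`, `y`, `z` plus the chain id as an attribute.
#' @export
read_structure <- function(path, chain) {
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  a <- a[a$chain == chain & a$elety == "CA" & a$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (nrow(a) == 0) stop("no CA records for chain '", chain, "'")
  if (is.null(a$o)) a$o <- 1
  a$o[is.na(a$o)] <- 1
  ## altloc: keep highest occupancy per residue number
  a <- a[order(a$resno, -a$o), , drop = FALSE]
  a <- a[!duplicated(a$resno), , drop = FALSE]
  stop_if_not(all(is.finite(a$x)) && all(is.finite(a$y)) && all(is.finite(a$z)),
              "non-finite coordinates")
  out <- data.frame(resno = a$resno, x = a$x, y = a$y, z = a$z)
  attr(out, "chain") <- chain
  class(out) <- c("ca_structure", "data.frame")
  out
}

#' Pairwise CA-CA distance
#'
#' @param struct A `ca_structure`.
#' @param res1,res2 Residue numbers (res2 may be a vector).
#' @return Euclidean distance(s) in the coordinate units (angstroms).
#' @export
ca_distance <- function(struct, res1, res2) {
  i <- match(res1, struct$resno)
  j <- match(res2, struct$resno)
  if (anyNA(c(i, j))) stop("residue(s) not in structure")
  sqrt((struct$x[j] - struct$x[i])^2 +
       (struct$y[j] - struct$y[i])^2 +
       (struct$z[j] - struct$z[i])^2)
}

#' Read an ouabain-assay well table
#'
#' Expects the long CSV layout `construct, background, substitution,
#' replicate, conc_M, absorbance, well_type` with `well_type` one of
#' `"ouabain"` (dose wells), `"control"` (no-ouabain experimental control)
#' or `"background"` (inhibition control measuring background phosphate).
#' `conc_M` is `NA` for control/background wells.
#'
#' @param path CSV file.
#' @return Validated data frame.
#' @export
read_assay_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("construct", "background", "substitution", "replicate",
            "conc_M", "absorbance", "well_type")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("assay table missing columns: ", paste(miss, collapse = ", "))
  stop_if_not(all(df$absorbance >= 0, na.rm = TRUE), "negative absorbances")
  stop_if_not(all(df$well_type %in% c("ouabain", "control", "background")),
              "well_type must be ouabain/control/background")
  df
}
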