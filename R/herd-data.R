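#' Read a herd characteristics table
#'
#' CSV with one row per animal: `animal_id`, age (mo), gestation stage (mo),
#' BW (kg), BCS, volume (m^3), hip width, withers height, chest depth, heart
#' girth, buttocks width (mm) and calving date.
#'
#' @param path CSV file path.
#' @return a data.frame.
#' @export
readHerdTable <- function(path) {
  if (!file.exists(path)) bcsStop("formatError", sprintf("no such file: %s", path))
  herd <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"animal_id" %in% names(herd))
    bcsStop("formatError", sprintf("herd table needs an animal_id column: %s", path))
  if (anyDuplicated(herd$animal_id))
    bcsStop("formatError", sprintf("duplicate animal_id rows: %s", path))
  herd
}

#' The packaged 13-heifer characteristics table
#'
#' Start-of-experiment characteristics of the 13 gestating Holstein heifers
#' (age, gestation stage, body weight, manual BCS, body volume and
#' morphological traits measured by the imaging rig). Serves as the default
#' morphology reference of the synthetic generator and as the herd-summary
#' fixture.
#'
#' @return a 13-row data.frame, see [readHerdTable()] for columns.
#' @export
heiferTable1 <- function() {
  readHerdTable(system.file("extdata", "table1_heifers.csv",
                            package = "bcs3d", mustWork = TRUE))
}
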