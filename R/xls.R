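# Minimal SpreadsheetML (Excel 2003 XML) writer. Plain-text format that Excel
# and LibreOffice open as a multi-sheet workbook; used because the batch
# output contract includes a spreadsheet alongside the CSVs.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Write data frames as a SpreadsheetML workbook
#'
#' @param tables Named list of data frames; one worksheet per element.
#' @param path Output path (conventionally `.xls`).
#' @return `path`, invisibly.
#' @export
write_xls <- function(tables, path) {
  stopifnot(is.list(tables), length(tables) > 0, !is.null(names(tables)))
  sheet <- function(name, df) {
    header <- paste0(
      "<Row>",
      paste0("<Cell><Data ss:Type=\"String\">", xml_escape(names(df)),
             "</Data></Cell>", collapse = ""),
      "</Row>"
    )
    rows <- vapply(seq_len(nrow(df)), function(i) {
      cells <- vapply(seq_along(df), function(j) {
        v <- df[[j]][i]
        if (is.na(v)) return("<Cell/>")
        if (is.numeric(v)) {
          sprintf("<Cell><Data ss:Type=\"Number\">%s</Data></Cell>",
                  format(v, digits = 15, scientific = FALSE))
        } else {
          sprintf("<Cell><Data ss:Type=\"String\">%s</Data></Cell>",
                  xml_escape(as.character(v)))
        }
      }, character(1))
      paste0("<Row>", paste0(cells, collapse = ""), "</Row>")
    }, character(1))
    paste0("<Worksheet ss:Name=\"", xml_escape(name), "\"><Table>",
           header, paste0(rows, collapse = ""), "</Table></Worksheet>")
  }
  body <- paste0(mapply(sheet, names(tables), tables), collapse = "\n")
  writeLines(c(
    "<?xml version=\"1.0\"?>",
    "<?mso-application progid=\"Excel.Sheet\"?>",
    paste0("<Workbook xmlns=\"urn:schemas-microsoft-com:office:spreadsheet\" ",
           "xmlns:ss=\"urn:schemas-microsoft-com:office:spreadsheet\">"),
    body,
    "</Workbook>"
  ), path)
  invisible(path)
}
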