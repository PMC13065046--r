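#' Result tables with provenance
#'
#' Every analysis serialises to a tibble carrying a provenance attribute:
#' input files, parameters, seed and tool version. Tables round-trip
#' losslessly through the TSV and JSON writers (provenance is stored in
#' `#` header lines for TSV and in a `provenance` block for JSON).
#'
#' @param data A data frame of results.
#' @param params Named list of analysis parameters.
#' @param inputs Character vector of input file paths (may be empty).
#' @param seed Integer seed, or `NA` when the analysis is deterministic.
#' @return A tibble of class `result_table`.
#' @export
result_table <- function(data, params = list(), inputs = character(), seed = NA_integer_) {
  tbl <- as_tibble(data)
  attr(tbl, "provenance") <- list(
    tool = "memflux",
    version = as.character(packageVersion("memflux")),
    inputs = as.character(inputs),
    params = params,
    seed = seed
  )
  class(tbl) <- c("result_table", class(tbl))
  tbl
}

#' @rdname result_table
#' @param x Object to query.
#' @export
provenance <- function(x) attr(x, "provenance")

#' Write or read a result table
#'
#' TSV output has `#`-prefixed provenance lines, a single header row, and one
#' row per record. JSON output is an object with `provenance`, `columns` and
#' `data` fields. Reading back either format restores an identical table.
#'
#' @param table A [result_table()] (a plain data frame is promoted).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param empty_ok Allow writing a zero-row table.
#' @return `path` invisibly (writer); a `result_table` (reader).
#' @export
write_result <- function(table, path, format = c("tsv", "json"), empty_ok = FALSE) {
  format <- match.arg(format)
  if (!inherits(table, "result_table")) table <- result_table(table)
  if (nrow(table) == 0L && !empty_ok) {
    abort("refusing to write an empty table; pass empty_ok = TRUE if intended")
  }
  prov <- provenance(table)
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# provenance: ",
                      jsonlite::toJSON(prov, auto_unbox = TRUE, digits = NA, null = "null")),
               con)
    df <- as.data.frame(table)
    # list-columns are serialised as comma-joined strings
    for (cn in names(df)) if (is.list(df[[cn]])) {
      df[[cn]] <- vapply(df[[cn]], function(v) paste(v, collapse = ","), character(1))
    }
    suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE, na = "NA"))
  } else {
    obj <- list(provenance = prov,
                columns = names(table),
                data = as.data.frame(table))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", null = "null", na = "null")
  }
  invisible(path)
}

#' @rdname write_result
#' @export
read_result <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    lines <- readLines(path, warn = FALSE)
    hdr <- grep("^# provenance: ", lines, value = TRUE)
    prov <- if (length(hdr) > 0) {
      jsonlite::fromJSON(sub("^# provenance: ", "", hdr[1]), simplifyVector = TRUE)
    } else NULL
    body <- lines[!startsWith(lines, "#")]
    df <- read.table(text = paste(body, collapse = "\n"), sep = "\t",
                     header = TRUE, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    prov <- obj$provenance
    df <- as.data.frame(obj$data, stringsAsFactors = FALSE)
    if (nrow(df) > 0) df <- df[, obj$columns, drop = FALSE]
  }
  out <- result_table(df, params = if (is.null(prov)) list() else prov$params,
                      inputs = if (is.null(prov)) character() else prov$inputs,
                      seed = if (is.null(prov) || is.null(prov$seed)) NA_integer_ else prov$seed)
  out
}
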