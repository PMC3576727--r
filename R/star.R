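## Minimal STAR (Self-defining Text Archive and Retrieval) table I/O: the
## metadata carrier of the single-particle ecosystem.  One loop_ data
## block per table; values round-trip losslessly at >= 6 significant
## digits.

#' Write a data.frame as a STAR data block
#'
#' @param table a data.frame
#' @param path output file
#' @param block data block name
#' @return `path`, invisibly
#' @export
write_star <- function(table, path, block = "particles") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("data_%s", block), "", "loop_"), con)
  nm <- names(table)
  writeLines(sprintf("_%s #%d", nm, seq_along(nm)), con)
  if (nrow(table) > 0) {
    cols <- lapply(table, function(col) {
      if (is.numeric(col)) formatC(col, digits = 10, format = "g")
      else as.character(col)
    })
    writeLines(do.call(paste, cols), con)
  }
  invisible(path)
}

#' Read a STAR data block as a data.frame
#'
#' Parses the first (or named) `loop_` block; numeric columns are detected
#' automatically.  Malformed rows raise an error with the line number.
#'
#' @param path input file
#' @param block data block name, or NULL for the first block
#' @return data.frame
#' @export
read_star <- function(path, block = NULL) {
  lines <- readLines(path)
  stripped <- trimws(lines)
  blocks <- grep("^data_", stripped)
  if (length(blocks) == 0) stop("no data block found in ", path)
  start <- if (is.null(block)) blocks[1] else {
    hit <- which(stripped == paste0("data_", block))
    if (length(hit) == 0) stop("no data block '", block, "' in ", path)
    hit[1]
  }
  end <- c(blocks[blocks > start], length(lines) + 1)[1] - 1
  body <- stripped[start:end]
  loop <- grep("^loop_", body)
  if (length(loop) == 0) stop("no loop_ in data block (line ",
                              start, ")")
  i <- loop[1] + 1
  cols <- character(0)
  while (i <= length(body) && grepl("^_", body[i])) {
    cols <- c(cols, sub("^_([^ #]+).*$", "\\1", body[i]))
    i <- i + 1
  }
  if (anyDuplicated(cols)) stop("duplicate column names in STAR header")
  rows <- if (i > length(body)) character(0) else body[i:length(body)]
  rows <- rows[nzchar(rows) & !grepl("^#", rows)]
  if (length(rows) == 0)
    return(stats::setNames(as.data.frame(matrix(nrow = 0,
                                                ncol = length(cols))),
                           cols))
  fields <- strsplit(rows, "[ \t]+")
  bad <- which(vapply(fields, length, integer(1)) != length(cols))
  if (length(bad) > 0)
    stop(sprintf("malformed STAR row at line %d: %d fields, expected %d",
                 start + loop[1] + length(cols) + bad[1] - 1,
                 length(fields[[bad[1]]]), length(cols)))
  m <- do.call(rbind, fields)
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- cols
  for (j in seq_along(out)) {
    num <- suppressWarnings(as.numeric(out[[j]]))
    if (!anyNA(num)) out[[j]] <- num
  }
  out
}

## pose table <-> STAR conventions: angles in degrees, offsets in both
## pixels and Angstrom (pixel size recorded per row)
pose_table_star <- function(pose_table, pixel_size) {
  data.frame(particle = pose_table$particle,
             half = pose_table$half,
             rot = pose_table$rot, tilt = pose_table$tilt,
             psi = pose_table$psi,
             offset_x_px = pose_table$offset_x,
             offset_y_px = pose_table$offset_y,
             offset_x_ang = pose_table$offset_x * pixel_size,
             offset_y_ang = pose_table$offset_y * pixel_size,
             pixel_size = pixel_size)
}
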