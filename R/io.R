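#' Write / read umbrella windows as TSV
#'
#' Long-format table (`dR0`, `k_bias`, `sample`) with a unit header comment;
#' round-trips through [read_windows()].
#'
#' @param windows list of umbrella windows.
#' @param path file path.
#' @export
write_windows <- function(windows, path) {
  tab <- do.call(rbind, lapply(windows, function(w)
    data.frame(dR0 = w$dR0, k_bias = w$k_bias, sample = w$samples)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# umbrella windows; dR0 and sample in nm, k_bias in kBT/nm^2",
             con)
  write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  lapply(split(tab, interaction(tab$dR0, tab$k_bias, drop = TRUE)),
         function(d) new_window(d$dR0[1], d$k_bias[1], d$sample))
}

#' Write / read a PMF table as TSV
#'
#' Columns `dR` (nm), `W` (kBT), `counts`; anchoring state and offsets are
#' preserved in header comments.
#'
#' @param pmf an `ncav_pmf`.
#' @param path file path.
#' @export
write_pmf <- function(pmf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# potential of mean force; dR in nm, W in kBT",
               sprintf("# anchored=%s", isTRUE(attr(pmf, "anchored"))),
               sprintf("# bin_width=%.10g", attr(pmf, "bin_width"))), con)
  write.table(as.data.frame(pmf), con, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_pmf
#' @export
read_pmf <- function(path) {
  lines <- readLines(path, n = 5)
  anchored <- any(grepl("anchored=TRUE", lines))
  bw <- regmatches(lines, regexec("bin_width=([-0-9.eE+]+)", lines))
  bw <- as.numeric(unlist(lapply(bw, `[`, 2)))
  bw <- bw[!is.na(bw)][1]
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  structure(tab, anchored = anchored, bin_width = bw,
            class = c("ncav_pmf", "data.frame"))
}

#' Run manifest
#'
#' Writes a JSON manifest recording the seed, configuration snapshot and
#' output paths of a pipeline stage, so that every output file is traceable
#' to exactly one manifest.
#'
#' @param path manifest path (JSON).
#' @param stage stage name.
#' @param seed integer seed used.
#' @param config configuration snapshot (list).
#' @param outputs named list/character vector of output paths.
#' @export
write_manifest <- function(path, stage, seed, config, outputs) {
  jsonlite::write_json(
    list(stage = stage, seed = seed,
         package = "ncavidity",
         version = as.character(utils::packageVersion("ncavidity")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config = config, outputs = as.list(outputs)),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
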