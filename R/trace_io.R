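#' Write / read a trace file
#'
#' Traces are stored as plain CSV with a small commented header recording
#' the configuration hash, preset and protocol events.  Reading back a
#' written trace reproduces the numeric columns to 1e-9 relative tolerance
#' and the events verbatim.
#'
#' @param trace A \code{leg_trace}.
#' @param path File path.
#' @return \code{write_trace} returns \code{path} invisibly;
#'   \code{read_trace} returns a \code{leg_trace}.
#' @export
write_trace <- function(trace, path) {
  stopifnot(is.data.frame(trace))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# sticksearch trace v1", con)
  writeLines(paste0("# preset: ", attr(trace, "preset")), con)
  writeLines(paste0("# config_hash: ", attr(trace, "config_hash")), con)
  ev <- attr(trace, "events")
  for (nm in names(ev))
    writeLines(paste0("# event ", nm, ": ", format(ev[[nm]], digits = 15)),
               con)
  cols <- vapply(trace, function(x)
    if (is.numeric(x)) format(x, digits = 15, trim = TRUE, scientific = FALSE)
    else as.character(x), character(nrow(trace)))
  writeLines(paste(names(trace), collapse = ","), con)
  writeLines(apply(cols, 1, paste, collapse = ","), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  body <- lines[!is_hdr]
  if (!length(body)) stop("malformed trace file (no data): ", path)
  tr <- tryCatch(
    utils::read.csv(text = body, stringsAsFactors = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e)))
  need <- c("time_ms", "beta_deg", "gamma_deg", "alpha_deg")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    stop("parse error in ", path, " (line ", sum(is_hdr) + 1,
         "): missing column(s) ", paste(miss, collapse = ", "))
  events <- list()
  preset <- NA_character_
  hash <- NA_character_
  for (h in hdr) {
    if (grepl("^# preset: ", h)) preset <- sub("^# preset: ", "", h)
    if (grepl("^# config_hash: ", h)) hash <- sub("^# config_hash: ", "", h)
    if (grepl("^# event ", h)) {
      kv <- sub("^# event ", "", h)
      k <- sub(":.*$", "", kv)
      v <- trimws(sub("^[^:]*:", "", kv))
      vn <- suppressWarnings(as.numeric(v))
      events[[k]] <- if (is.na(vn)) v else vn
    }
  }
  attr(tr, "preset") <- preset
  attr(tr, "config_hash") <- hash
  attr(tr, "events") <- events
  class(tr) <- c("leg_trace", "data.frame")
  tr
}
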