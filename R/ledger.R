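# Sample-ledger CSV I/O. Plain CSV with a '#'-prefixed metadata preamble so
# files are greppable and diff-able; the protonation column is a fixed-length
# 0/1 string in the model's canonical site order.

#' Write a sample ledger to CSV
#'
#' @param ledger A `sample_ledger` from [run_ph_remd()] or [run_fixed_ph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  stopifnot(inherits(ledger, "sample_ledger"))
  sched <- attr(ledger, "schedule")
  meta <- c(
    "# phlinkage sample ledger",
    sprintf("# model: %s", attr(ledger, "label")),
    sprintf("# seed: %d", sched$seed),
    sprintf("# schedule: n_attempts=%d,conformer_move_prob=%g,exchange_interval=%d,burn_in_fraction=%.10g,thin=%d",
            sched$n_attempts, sched$conformer_move_prob,
            sched$exchange_interval, sched$burn_in_fraction, sched$thin),
    sprintf("# exchange: %s", if (isTRUE(attr(ledger, "exchange"))) "on" else "off"),
    sprintf("# sites: %s", paste(attr(ledger, "sites"), collapse = ",")),
    sprintf("# ladder: %s", paste(format(attr(ledger, "ladder"), trim = TRUE),
                                  collapse = ","))
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines("replica,attempt,pH,conformer,protonation,N", con)
  writeLines(paste(ledger$replica, ledger$attempt,
                   format(ledger$pH, trim = TRUE, digits = 15),
                   ledger$conformer, ledger$protonation, ledger$N, sep = ","),
             con)
  invisible(path)
}

#' Read a sample ledger from CSV
#'
#' Losslessly restores a ledger written by [write_ledger()], including the
#' metadata preamble (model label, seed, schedule, site order, pH ladder).
#'
#' @param path File path.
#' @return A `sample_ledger` data frame.
#' @export
read_ledger <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- startsWith(lines, "#")
  meta <- lines[is_meta]
  body <- lines[!is_meta]
  if (length(body) < 1L) stop("ledger file has no header row")

  get_meta <- function(key) {
    hit <- grep(sprintf("^# %s:", key), meta, value = TRUE)
    if (!length(hit)) stop(sprintf("ledger metadata missing '# %s:' line", key))
    sub(sprintf("^# %s:\\s*", key), "", hit[1])
  }
  label <- get_meta("model")
  seed <- as.integer(get_meta("seed"))
  sites <- strsplit(get_meta("sites"), ",", fixed = TRUE)[[1]]
  ladder <- as.numeric(strsplit(get_meta("ladder"), ",", fixed = TRUE)[[1]])
  exchange <- identical(get_meta("exchange"), "on")
  sched_kv <- strsplit(strsplit(get_meta("schedule"), ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
  sched_vals <- setNames(vapply(sched_kv, `[`, character(1), 2L),
                         vapply(sched_kv, `[`, character(1), 1L))
  schedule <- mc_schedule(
    n_attempts = as.numeric(sched_vals[["n_attempts"]]),
    conformer_move_prob = as.numeric(sched_vals[["conformer_move_prob"]]),
    exchange_interval = as.numeric(sched_vals[["exchange_interval"]]),
    burn_in_fraction = as.numeric(sched_vals[["burn_in_fraction"]]),
    thin = as.numeric(sched_vals[["thin"]]),
    seed = seed)

  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  required <- c("replica", "attempt", "pH", "conformer", "protonation", "N")
  missing_cols <- setdiff(required, header)
  if (length(missing_cols)) {
    stop(sprintf("ledger missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  rows <- body[-1]
  nfield <- lengths(strsplit(rows, ",", fixed = TRUE))
  bad <- which(nfield != length(header))
  if (length(bad)) {
    stop(sprintf("malformed ledger row %d: expected %d fields, found %d",
                 bad[1], length(header), nfield[bad[1]]))
  }
  fields <- do.call(rbind, strsplit(rows, ",", fixed = TRUE))
  colnames(fields) <- header
  ledger <- data.frame(
    replica = as.integer(fields[, "replica"]),
    attempt = as.integer(fields[, "attempt"]),
    pH = as.numeric(fields[, "pH"]),
    conformer = fields[, "conformer"],
    protonation = fields[, "protonation"],
    N = as.integer(fields[, "N"]),
    stringsAsFactors = FALSE)

  badlen <- which(nchar(ledger$protonation) != length(sites))
  if (length(badlen)) {
    stop(sprintf("ledger row %d: protonation string length %d does not match %d sites",
                 badlen[1], nchar(ledger$protonation[badlen[1]]), length(sites)))
  }
  if (!all(ledger$pH %in% ladder)) {
    stop("ledger contains pH values absent from its ladder metadata")
  }
  attr(ledger, "sites") <- sites
  attr(ledger, "ladder") <- ladder
  attr(ledger, "label") <- label
  attr(ledger, "schedule") <- schedule
  attr(ledger, "exchange") <- exchange
  class(ledger) <- c("sample_ledger", "data.frame")
  ledger
}
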