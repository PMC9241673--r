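# Command-line dispatcher behind the exec/seqops script:
#   seqops {rc|cpg|sym16|knuc|seed|gen} [flags]
# Results go to stdout (or --out); logging to stderr with --verbose;
# exit code 0 on success, 2 on input format errors. A --config file of
# key=value lines may set defaults for k, step, M, workers and
# batch-size; explicit flags override it.

read_config <- function(path) {
  if (is.null(path)) return(list())
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nchar(trimws(lines)) > 0 & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(p) trimws(p[2L])),
                  vapply(kv, function(p) trimws(p[1L]), ""))
}

cli_value <- function(opts, config, flag, default) {
  v <- opts[[flag]]
  if (!is.null(v) && !is.na(v)) return(v)
  cf <- config[[gsub("_", "-", flag)]]
  if (!is.null(cf)) {
    return(if (is.integer(default)) as.integer(cf)
           else if (is.numeric(default)) as.numeric(cf)
           else as.character(cf))
  }
  default
}

#' Command-line entry point
#'
#' Implements `seqops {rc|cpg|sym16|knuc|seed|gen}`; see the
#' `exec/seqops` script. Not usually called directly from R -- the
#' `cmd_*` functions are the programmatic interface.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 success, 1 usage error, 2 format
#'   error).
#' @export
seqops_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: seqops <command> [flags]",
    "commands:",
    "  rc     --in FILE [--out FILE] [--workers N] [--batch-size N]",
    "  cpg    --in FILE [--workers N]",
    "  sym16  --in FILE [--stride N] [--workers N]",
    "  knuc   --in FILE [--k LIST] [--query LIST]",
    "  seed   --ref FILE --in FILE [--k N] [--step N] [--prefetch]",
    "         [--M N] [--out FILE]",
    "  gen    --what reads|reference --out FILE [--n N] [--len N]",
    "         [--n-rate P] [--seed N]",
    "common: [--config FILE] [--verbose]",
    sep = "\n")
  if (!length(args) || args[1L] %in% c("-h", "--help")) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  if (!requireNamespace("optparse", quietly = TRUE)) {
    message("the 'optparse' package is required for the CLI")
    return(invisible(1L))
  }
  cmd <- args[1L]
  rest <- args[-1L]
  o <- optparse::make_option
  opts_spec <- list(
    o("--in", dest = "input", type = "character"),
    o("--out", type = "character"),
    o("--ref", type = "character"),
    o("--k", type = "character", default = NA_character_),
    o("--step", type = "integer", default = NA_integer_),
    o("--stride", type = "integer", default = NA_integer_),
    o("--workers", type = "integer", default = NA_integer_),
    o("--batch-size", dest = "batch_size", type = "integer",
      default = NA_integer_),
    o("--M", dest = "M", type = "integer", default = NA_integer_),
    o("--prefetch", action = "store_true", default = FALSE),
    o("--what", type = "character", default = "reads"),
    o("--n", type = "integer", default = 1000L),
    o("--len", type = "integer", default = NA_integer_),
    o("--n-rate", dest = "n_rate", type = "double", default = 0),
    o("--query", type = "character", default = NA_character_),
    o("--seed", type = "integer", default = 1L),
    o("--config", type = "character", default = NULL),
    o("--verbose", action = "store_true", default = FALSE))
  opts <- tryCatch(
    optparse::parse_args(optparse::OptionParser(option_list = opts_spec),
                         args = rest),
    error = function(e) {
      message(conditionMessage(e))
      NULL
    })
  if (is.null(opts)) return(invisible(1L))
  config <- read_config(opts$config)
  log_msg <- function(...) if (isTRUE(opts$verbose)) message("seqops: ", ...)
  emit <- function(lines) {
    if (!is.null(opts$out) && cmd != "rc" && cmd != "seed") {
      writeLines(lines, opts$out)
    } else {
      writeLines(lines)
    }
  }

  status <- tryCatch({
    if (cmd == "rc") {
      workers <- cli_value(opts, config, "workers", 1L)
      bs <- cli_value(opts, config, "batch_size", 100000L)
      out <- if (is.null(opts$out)) stdout() else opts$out
      log_msg("reverse complementing ", opts$input)
      n <- if (is.null(opts$out)) {
        recs <- cmd_rc(opts$input, output = NULL, workers = workers,
                       batch_size = bs)
        for (r in recs) cat("@", r$name, "\n", r$seq, "\n+\n", r$qual, "\n",
                            sep = "")
        length(recs)
      } else {
        cmd_rc(opts$input, opts$out, workers = workers, batch_size = bs)
      }
      log_msg(n, " reads written")
      0L
    } else if (cmd == "cpg") {
      r <- cmd_cpg(opts$input,
                   workers = cli_value(opts, config, "workers", 1L),
                   batch_size = cli_value(opts, config, "batch_size",
                                          100000L))
      emit(sprintf("count\t%d\nmin_len\t%d\nmax_len\t%d",
                   r$count, r$min_len, r$max_len))
      0L
    } else if (cmd == "sym16") {
      n <- cmd_sym16(opts$input,
                     stride = cli_value(opts, config, "stride", 1L),
                     workers = cli_value(opts, config, "workers", 1L))
      emit(sprintf("symmetric_16mers\t%d", n))
      0L
    } else if (cmd == "knuc") {
      ks <- if (is.na(opts$k)) c(1L, 2L) else
        as.integer(strsplit(opts$k, ",", fixed = TRUE)[[1L]])
      qs <- if (is.na(opts$query)) character(0) else
        strsplit(opts$query, ",", fixed = TRUE)[[1L]]
      r <- cmd_knuc(opts$input, k = ks, queries = qs)
      lines <- character(0)
      for (kk in names(r$freq)) {
        f <- r$freq[[kk]]
        lines <- c(lines, sprintf("%s\t%.6f", names(f), f), "")
      }
      if (length(r$counts)) {
        lines <- c(lines, sprintf("%d\t%s", r$counts, names(r$counts)))
      }
      emit(lines)
      0L
    } else if (cmd == "seed") {
      kk <- if (is.na(opts$k)) 20L else as.integer(opts$k)
      kk <- cli_value(list(k = kk), config, "k", kk)
      df <- cmd_seed(opts$ref, opts$input, k = kk,
                     step = if (is.na(opts$step)) NULL else opts$step,
                     prefetch = isTRUE(opts$prefetch),
                     M = cli_value(opts, config, "M", 16L))
      lines <- c("name\thits_forward\thits_reverse",
                 sprintf("%s\t%d\t%d", df$name, df$hits_forward,
                         df$hits_reverse))
      if (is.null(opts$out)) writeLines(lines) else writeLines(lines,
                                                               opts$out)
      0L
    } else if (cmd == "gen") {
      len <- if (is.na(opts$len)) {
        if (opts$what == "reads") 75L else 100000L
      } else opts$len
      cmd_gen(opts$what, opts$out, n_reads = opts$n, read_length = len,
              n_rate = opts$n_rate, length = len, seed = opts$seed)
      log_msg("wrote ", opts$out)
      0L
    } else {
      message("unknown command: ", cmd, "\n", usage)
      1L
    }
  }, seqops_error = function(e) {
    message("seqops: ", conditionMessage(e))
    2L
  }, error = function(e) {
    message("seqops: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
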