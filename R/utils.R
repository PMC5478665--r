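# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library calls never perturb user-level randomness.
run_seeded <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Small deterministic polynomial hash of a string; used for sub-seed
# derivation and provenance hashes. Arithmetic kept below 2^53 so results
# are exact in doubles; output in [0, 2^31 - 2].
text_hash <- function(x) {
  h <- 0
  for (b in utf8ToInt(paste(as.character(x), collapse = "\x1f"))) {
    h <- (h * 131 + b) %% 2147483647
  }
  h
}

# Deterministic sub-seed from arbitrary components (cohort seed, group name,
# track index, ...). Independent of generation order.
derive_seed <- function(...) {
  parts <- vapply(list(...), function(p) paste(format(p), collapse = ","),
                  character(1))
  (text_hash(paste(parts, collapse = "|")) %% 2147483629L) + 1
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || (strict_lower && x <= lower) || x > upper) {
    stop(sprintf("'%s' = %g out of range [%g, %g]%s", name, x, lower, upper,
                 if (strict_lower) " (exclusive lower bound)" else ""),
         call. = FALSE)
  }
  invisible(x)
}

check_probability <- function(x, name) check_number(x, name, 0, 1)

# key=value text (flat config / sidecar metadata) ------------------------

write_keyvalue <- function(values, path) {
  stopifnot(is.list(values) || is.character(values))
  lines <- vapply(names(values), function(k) {
    sprintf("%s=%s", k, paste(format(values[[k]], digits = 15), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

read_keyvalue <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    stop("malformed key=value line: ", lines[which(bad)[1]], call. = FALSE)
  }
  out <- lapply(kv, function(p) trimws(p[2]))
  names(out) <- vapply(kv, function(p) trimws(p[1]), character(1))
  out
}

kv_number <- function(kv, key, required = TRUE) {
  if (is.null(kv[[key]])) {
    if (required) stop("missing required metadata key: ", key, call. = FALSE)
    return(NULL)
  }
  as.numeric(kv[[key]])
}

# CSV with '#'-prefixed provenance header lines --------------------------

write_csv_prov <- function(df, file, provenance = list()) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# kymoquant %s",
                     as.character(utils::packageVersion("kymoquant"))), con)
  for (k in names(provenance)) {
    writeLines(sprintf("# %s=%s", k,
                       paste(format(provenance[[k]], digits = 15),
                             collapse = ",")), con)
  }
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(file)
}

read_csv_prov <- function(file) {
  utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
}
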