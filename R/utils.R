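# Internal helpers: classed conditions, tiny hash, misc.

`%||%` <- function(a, b) if (is.null(a)) b else a

cw_abort <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "cw_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

cw_config_error     <- function(msg, ...) cw_abort("cw_config_error", msg, ...)
cw_schema_error     <- function(msg, ...) cw_abort("cw_schema_error", msg, ...)
cw_validation_error <- function(msg, ...) cw_abort("cw_validation_error", msg, ...)
cw_structural_error <- function(msg, ...) cw_abort("cw_structural_error", msg, ...)
cw_separation_error <- function(msg, ...) cw_abort("cw_separation_error", msg, ...)
cw_divergence_error <- function(msg, ...) cw_abort("cw_divergence_error", msg, ...)

# FNV-1a 32-bit over a string; deterministic node ids without extra deps.
cw_hash32 <- function(x) {
  h <- 2166136261
  for (b in utf8ToInt(enc2utf8(x))) {
    # xor only touches the low byte since b < 256; keep h a double in [0, 2^32)
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    # 32-bit multiply by the FNV prime 16777619 in 16-bit halves so every
    # intermediate stays below 2^53 (exact in doubles)
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Whole days in [a, b): b - a.
cw_days <- function(from, to) as.integer(as.numeric(to) - as.numeric(from))

# Age in completed years at `on` for someone born `birth`.
cw_age_years <- function(birth, on) {
  bl <- as.POSIXlt(birth); ol <- as.POSIXlt(on)
  age <- ol$year - bl$year
  before <- (ol$mon < bl$mon) | (ol$mon == bl$mon & ol$mday < bl$mday)
  as.integer(age - before)
}

cw_parse_date <- function(x, context) {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x) & nzchar(x))
  if (length(bad) > 0) {
    cw_validation_error(sprintf(
      "%s: unparseable date '%s' at row %d (expected YYYY-MM-DD)",
      context, x[bad[1]], bad[1]))
  }
  if (anyNA(d)) {
    cw_validation_error(sprintf("%s: missing date at row %d", context, which(is.na(d))[1]))
  }
  d
}

cw_stopifnot_cols <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    cw_schema_error(sprintf("table '%s' is missing column(s): %s",
                            table, paste(missing, collapse = ", ")))
  }
}
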