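# Internal helpers: classed conditions and small utilities.

`%||%` <- function(a, b) if (is.null(a)) b else a

# All package errors carry a subclass so callers (and the CLI wrapper) can
# distinguish usage/configuration problems from data or numerical failures.
stop_habrep <- function(subclass, message, data = NULL) {
  cond <- structure(
    class = c(paste0("habrep_", subclass), "habrep_error", "error", "condition"),
    list(message = message, call = sys.call(-1), data = data)
  )
  stop(cond)
}

warn_habrep <- function(subclass, message, data = NULL) {
  cond <- structure(
    class = c(paste0("habrep_", subclass), "habrep_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1), data = data)
  )
  warning(cond)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

# md5 of an in-memory object via its canonical JSON serialization; used to
# stamp outputs with an input digest without adding a hashing dependency.
digest_object <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

digest_file <- function(path) unname(tools::md5sum(path))

# all permutations of seq_len(n), as a list; n is guarded by callers
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", factorial(n))
  k <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (p in sub) {
      k <- k + 1L
      out[[k]] <- c(i, rest[p])
    }
  }
  out
}
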