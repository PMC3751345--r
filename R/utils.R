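# Internal helpers shared across modules.

STRANDS <- c("forward", "reverse", "unstranded")
MARKER_KINDS <- c("gene", "variant", "microsatellite", "sequence",
                  "assembly_exception", "generic")
MAP_UNITS <- c("bp", "cM", "arbitrary")
HOMOLOGY_TYPES <- c("ortholog_one2one", "apparent_ortholog_one2one",
                    "ortholog_one2many", "ortholog_many2many",
                    "possible_ortholog", "paralog")
LINK_TYPES <- c("identity", "synonymy", HOMOLOGY_TYPES)

sm_abort <- function(msg, class, ...) {
  stop(structure(class = c(class, "synmapr_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

sm_assert <- function(ok, msg, class = "synmapr_invalid") {
  if (!isTRUE(ok)) sm_abort(msg, class)
  invisible(TRUE)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic number formatter used by all writers: whole numbers print
# without decimals, everything else with up to 15 significant digits
# (round-trips coordinates with <= 6 decimal places exactly).
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("")
    if (v == floor(v) && abs(v) < 1e15) sprintf("%.0f", v)
    else sprintf("%.15g", v)
  }, character(1))
}

# Fixed-precision formatter for canvas/SVG geometry (bit-stable output).
fmt_px <- function(x) {
  s <- sprintf("%.3f", x)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
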