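# Internal helpers shared across modules.

# The twenty standard one-letter amino-acid codes, alphabetical.
AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

# Deterministic child-seed derivation: one global seed fans out to
# per-generator seeds by a fixed counter scheme, so adding a generator
# never perturbs fixtures produced by existing ones. Kept below 2^31.
child_seed <- function(seed, index) {
  stopifnot(length(seed) == 1L, length(index) == 1L, index >= 0L)
  as.integer(((as.numeric(seed) %% 2147483647) * 1009 + index) %%
               2147483647)
}

is_aa1 <- function(x) x %in% AA1

# One-letter sequence of a structure_model via its 3-letter residue names.
model_seq1 <- function(model) {
  paste(bio3d::aa321(model$resid), collapse = "")
}
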