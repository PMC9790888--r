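# Stage codes for deterministic per-operation RNG substreams.
.stage_codes <- c(init = 1L, propose = 2L, surrogate = 3L, screen = 4L,
                  bulls = 5L, assay = 6L, folds = 7L, select = 8L)

#' Derive a deterministic substream seed
#'
#' Every stochastic stage of a campaign seeds R's generator from a value that
#' depends only on the campaign seed, the generation number and a stage label.
#' A resumed campaign therefore replays the identical random stream regardless
#' of how many draws earlier generations consumed, which is what makes ledgers
#' byte-identical under resume-from-prefix.
#'
#' @param seed campaign-level integer seed.
#' @param generation generation number (0 for initialization).
#' @param stage one of `"init"`, `"propose"`, `"surrogate"`, `"screen"`,
#'   `"bulls"`, `"assay"`, `"folds"`, `"select"`.
#' @return an integer seed below 2^31.
#' @export
substream_seed <- function(seed, generation, stage) {
  stage <- match.arg(stage, names(.stage_codes))
  code <- .stage_codes[[stage]]
  as.integer((as.numeric(seed) %% 65011 * 33029 +
                as.numeric(generation) * 1009 + code * 101) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
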