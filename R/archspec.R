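#' Analytic network shape inference and parameter counting
#'
#' A declarative registry of the benchmarked network architectures
#' together with a shape-inference engine that derives every layer's
#' output shape and trainable-parameter count analytically -- no learning
#' framework required. Counting rules (Keras conventions):
#' \itemize{
#'   \item conv1d: `filters * (kernel * in_channels + 1)`; output length
#'     `L` for `same` padding, `L - kernel + 1` for `valid`.
#'   \item dense: `in * out + out`.
#'   \item lstm: `4 * (units * (in + units) + units)`.
#'   \item gru (reset-after gating): `3 * (units*in + units^2 + 2*units)`.
#'   \item batchnorm: `4 * channels`; layernorm: `2 * channels`.
#'   \item multi-head attention (d_model = in channels):
#'     `4 * (d_model * heads * key_dim) + 3 * heads * key_dim + d_model`
#'     (query/key/value/output projections with biases).
#'   \item maxpool1d (`floor(L / pool)` length), dropout, flatten, input: 0.
#' }
#'
#' @name archspec
NULL

layer <- function(kind, ...) c(list(kind = kind), list(...))

#' Architecture registry
#'
#' Canonical layer lists of the benchmarked networks on a 600-sample
#' univariate input. Registry names: `cnn1d` (two conv/pool/dropout
#' blocks then dense-100, dense-1), `lstm2` and `gru2` (two stacked
#' 64-unit recurrent layers, dense-100, dense-1), `gan_disc` (the GAN
#' discriminator reused as a binary classifier), `rl_encoder` (the shared
#' convolutional encoder of the RL agents, with batch normalization), and
#' `transformer_enc` (a single attention encoder block; its total is a
#' nominal configuration, not a reference count).
#'
#' @param name Registry name.
#' @param input_len Input sequence length (default 600).
#' @return An object of class `arch_spec`.
#' @export
registry <- function(name, input_len = 600) {
  archs <- list(
    cnn1d = list(
      layer("conv1d", filters = 32, kernel = 5, padding = "same"),
      layer("maxpool1d", pool = 2),
      layer("dropout", rate = 0.3),
      layer("conv1d", filters = 64, kernel = 5, padding = "same"),
      layer("maxpool1d", pool = 2),
      layer("dropout", rate = 0.3),
      layer("flatten"),
      layer("dense", units = 100),
      layer("dense", units = 1)),
    lstm2 = list(
      layer("lstm", units = 64, return_sequences = TRUE),
      layer("dropout", rate = 0.3),
      layer("lstm", units = 64, return_sequences = FALSE),
      layer("dropout", rate = 0.3),
      layer("dense", units = 100),
      layer("dense", units = 1)),
    gru2 = list(
      layer("gru", units = 64, return_sequences = TRUE, reset_after = TRUE),
      layer("dropout", rate = 0.3),
      layer("gru", units = 64, return_sequences = FALSE, reset_after = TRUE),
      layer("dropout", rate = 0.3),
      layer("dense", units = 100),
      layer("dense", units = 1)),
    gan_disc = list(
      layer("conv1d", filters = 32, kernel = 8, padding = "valid"),
      layer("maxpool1d", pool = 4),
      layer("conv1d", filters = 64, kernel = 5, padding = "valid"),
      layer("maxpool1d", pool = 4),
      layer("flatten"),
      layer("dense", units = 64),
      layer("dense", units = 2)),
    rl_encoder = list(
      layer("conv1d", filters = 32, kernel = 8, padding = "valid"),
      layer("batchnorm"),
      layer("maxpool1d", pool = 4),
      layer("conv1d", filters = 64, kernel = 5, padding = "valid"),
      layer("batchnorm"),
      layer("maxpool1d", pool = 4),
      layer("flatten"),
      layer("dense", units = 128),
      layer("batchnorm"),
      layer("dropout", rate = 0.3),
      layer("dense", units = 64),
      layer("batchnorm")),
    transformer_enc = list(
      layer("mha", heads = 4, key_dim = 64),
      layer("layernorm"),
      layer("dense", units = 128),
      layer("dense", units = 1),
      layer("layernorm"),
      layer("flatten"),
      layer("dense", units = 1))
  )
  if (!name %in% names(archs))
    stop("unknown architecture '", name, "'; known: ",
         paste(names(archs), collapse = ", "))
  structure(list(name = name,
                 input_shape = c(length = input_len, channels = 1),
                 layers = archs[[name]],
                 canonical_total = !identical(name, "transformer_enc")),
            class = "arch_spec")
}

count_layer <- function(l, len, ch) {
  out_len <- len; out_ch <- ch; params <- 0
  switch(l$kind,
    input = NULL,
    conv1d = {
      if (l$padding == "valid") {
        if (l$kernel > len) stop("shape underflow: kernel exceeds length")
        out_len <- len - l$kernel + 1
      }
      out_ch <- l$filters
      params <- l$filters * (l$kernel * ch + 1)
    },
    maxpool1d = { out_len <- floor(len / l$pool) },
    dropout = NULL,
    flatten = { out_len <- 1; out_ch <- len * ch },
    dense = {
      # applies to the channel (last) dimension; len > 1 = time-distributed
      out_ch <- l$units
      params <- ch * l$units + l$units
    },
    lstm = {
      out_ch <- l$units
      if (!isTRUE(l$return_sequences)) out_len <- 1
      params <- 4 * (l$units * (ch + l$units) + l$units)
    },
    gru = {
      out_ch <- l$units
      if (!isTRUE(l$return_sequences)) out_len <- 1
      params <- if (isTRUE(l$reset_after))
        3 * (l$units * ch + l$units^2 + 2 * l$units)
      else
        3 * (l$units * (ch + l$units) + l$units)
    },
    batchnorm = { params <- 4 * ch },
    layernorm = { params <- 2 * ch },
    mha = {
      params <- 4 * (ch * l$heads * l$key_dim) +
        3 * l$heads * l$key_dim + ch
    },
    stop("unknown layer kind: ", l$kind))
  list(len = out_len, ch = out_ch, params = params)
}

#' Infer shapes and parameter counts for an architecture
#'
#' Chains the counting rules over the layer list, starting from the
#' declared input shape.
#'
#' @param arch An `arch_spec` from [registry()].
#' @return An object of class `shape_report`: data.frame with columns
#'   `kind`, `out_len`, `out_channels`, `params`, plus attribute
#'   `total_params`.
#' @export
infer <- function(arch) {
  stopifnot(inherits(arch, "arch_spec"))
  len <- arch$input_shape[["length"]]
  ch <- arch$input_shape[["channels"]]
  rows <- lapply(arch$layers, function(l) {
    r <- count_layer(l, len, ch)
    len <<- r$len; ch <<- r$ch
    data.frame(kind = l$kind, out_len = r$len, out_channels = r$ch,
               params = r$params)
  })
  rep <- do.call(rbind, rows)
  structure(rep, total_params = sum(rep$params), arch_name = arch$name,
            class = c("shape_report", "data.frame"))
}

#' @export
print.shape_report <- function(x, ...) {
  cat("<shape_report> ", attr(x, "arch_name"), "\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  cat("total trainable parameters:",
      format(attr(x, "total_params"), big.mark = ","), "\n")
  invisible(x)
}

#' Total parameter count of an architecture
#'
#' @param arch An `arch_spec` or registry name.
#' @param input_len Input length when `arch` is a name.
#' @return Integer total.
#' @export
total_params <- function(arch, input_len = 600) {
  if (is.character(arch)) arch <- registry(arch, input_len)
  attr(infer(arch), "total_params")
}

#' Cross-check analytic counts against an external reference
#'
#' Compares the analytic per-layer parameter counts against reference
#' counts produced by an external source (for example a deep-learning
#' framework's model summary). When no reference is supplied the check
#' is skipped cleanly -- the analytic engine is self-contained and no
#' training backend is assumed.
#'
#' @param arch An `arch_spec`.
#' @param reference_counts Optional numeric vector of per-layer counts in
#'   layer order.
#' @return List with `status` ("ok", "mismatch" or "skipped") and, when
#'   checked, a per-layer comparison data.frame.
#' @export
crosscheck <- function(arch, reference_counts = NULL) {
  rep <- infer(arch)
  if (is.null(reference_counts))
    return(list(status = "skipped",
                reason = "no reference parameter counts supplied"))
  if (length(reference_counts) != nrow(rep))
    stop("reference_counts length does not match the layer count")
  cmp <- data.frame(kind = rep$kind, analytic = rep$params,
                    reference = reference_counts,
                    match = rep$params == reference_counts)
  list(status = if (all(cmp$match)) "ok" else "mismatch", comparison = cmp)
}
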