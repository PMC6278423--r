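#' Assemble a scaled descriptor matrix from field blocks
#'
#' Columns whose (pre-scaling) standard deviation falls below `min_sigma`
#' are dropped; each surviving block is then rescaled so every block has
#' equal total variance ("CoMFA standard" block scaling: each field gets
#' the same potential influence).  Scale factors, column masks and column
#' statistics are stored so prediction rows can be built identically.
#'
#' @param blocks named list of `qsar_field_block` sharing the molecule
#'   axis.
#' @param min_sigma minimum column standard deviation (default 2.0, in the
#'   block's native units; use a smaller value for similarity fields,
#'   e.g. 0.005).
#' @return Object of class `qsar_descriptors`.
#' @export
assemble_descriptors <- function(blocks, min_sigma = 2.0) {
  stopifnot(length(blocks) >= 1)
  nmol <- unique(vapply(blocks, function(b) nrow(b$values), integer(1)))
  if (length(nmol) != 1) stop("field blocks disagree on the molecule axis")
  Xs <- list(); labels <- character(); col_index <- integer()
  sd_raw <- numeric(); mask_by_block <- list(); scale_factors <- numeric()
  for (b in names(blocks)) {
    V <- blocks[[b]]$values
    s <- apply(V, 2, stats::sd)
    keep <- s >= min_sigma
    mask_by_block[[b]] <- keep
    if (!any(keep)) { scale_factors[b] <- NA_real_; next }
    Vk <- V[, keep, drop = FALSE]
    f <- 1 / sqrt(sum(s[keep]^2))        # equalise per-block total variance
    scale_factors[b] <- f
    Xs[[b]] <- Vk * f
    labels <- c(labels, rep(b, ncol(Vk)))
    col_index <- c(col_index, which(keep))
    sd_raw <- c(sd_raw, s[keep])
  }
  if (!length(Xs))
    stop("all columns filtered out (min_sigma = ", min_sigma, ")")
  X <- do.call(cbind, Xs)
  structure(list(
    X = X,
    block_labels = labels,
    col_index = col_index,
    mask_by_block = mask_by_block,
    scale_factors = scale_factors,
    col_sd_raw = sd_raw,
    col_sd = sd_raw * scale_factors[labels],
    min_sigma = min_sigma,
    grid = blocks[[1]]$grid),
    class = "qsar_descriptors")
}

#' @export
print.qsar_descriptors <- function(x, ...) {
  cat(sprintf("<qsar_descriptors: %d molecules x %d columns (%s)>\n",
              nrow(x$X), ncol(x$X),
              paste(sprintf("%s:%d", unique(x$block_labels),
                            table(x$block_labels)[unique(x$block_labels)]),
                    collapse = ", ")))
  invisible(x)
}

#' Build prediction descriptor rows on a trained descriptor layout
#'
#' Applies the training column masks and block scale factors to new field
#' blocks (computed on the training grid, with training exclusion fill).
#'
#' @param desc `qsar_descriptors` from training.
#' @param blocks field blocks for the new molecules (same kinds and grid).
#' @return matrix of descriptor rows.
#' @export
descriptor_rows <- function(desc, blocks) {
  used <- names(desc$scale_factors)[!is.na(desc$scale_factors)]
  miss <- setdiff(used, names(blocks))
  if (length(miss))
    stop("missing field block(s) for prediction: ", paste(miss, collapse = ", "))
  parts <- lapply(used, function(b) {
    keep <- desc$mask_by_block[[b]]
    if (ncol(blocks[[b]]$values) != length(keep))
      stop("block '", b, "': column count mismatch with training grid")
    blocks[[b]]$values[, keep, drop = FALSE] * desc$scale_factors[b]
  })
  do.call(cbind, parts)
}
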