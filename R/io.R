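# TIFF, TSV and model serialization helpers. Intensities are 12-bit values
# in 16-bit containers; the tiff package stores [0, 1], so values are scaled
# by 65535 on write and back on read.

#' Write a two-channel micrograph as paired TIFF files
#'
#' @param micrograph List with `rfp` and `gfp` matrices (values 0..4095).
#' @param path Output path prefix; `_rfp.tif` and `_gfp.tif` are appended.
#' @return Invisibly, the two file paths.
#' @export
write_micrograph_tiff <- function(micrograph, path) {
  paths <- paste0(path, c("_rfp.tif", "_gfp.tif"))
  tiff::writeTIFF(pmin(pmax(micrograph$rfp, 0), 65535) / 65535, paths[1],
                  bits.per.sample = 16)
  tiff::writeTIFF(pmin(pmax(micrograph$gfp, 0), 65535) / 65535, paths[2],
                  bits.per.sample = 16)
  invisible(paths)
}

#' Read a paired-TIFF micrograph
#'
#' @param path Path prefix used by [write_micrograph_tiff()].
#' @return List with `rfp` and `gfp` matrices on the original value scale.
#' @export
read_micrograph_tiff <- function(path) {
  rd <- function(p) {
    m <- tiff::readTIFF(p)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m * 65535
  }
  list(rfp = rd(paste0(path, "_rfp.tif")), gfp = rd(paste0(path, "_gfp.tif")))
}

#' Write a float-valued map (posterior or edge distance) as 32-bit TIFF
#'
#' @param m Numeric matrix.
#' @param path Output file.
#' @export
write_float_tiff <- function(m, path) {
  scale <- max(m, 1)
  tiff::writeTIFF(m / scale, path, bits.per.sample = 32)
  invisible(path)
}

# TSV with '#' metadata header lines; floats at 6 significant digits.
write_table_tsv <- function(df, path, meta = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in meta) writeLines(paste0("# ", m), con)
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) {
      df[[j]] <- signif(df[[j]], 6)
    }
  }
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

read_table_tsv <- function(path) {
  tibble::as_tibble(read.table(path, header = TRUE, sep = "\t",
                               comment.char = "#", stringsAsFactors = FALSE))
}

#' Serialize a confidence model to JSON
#'
#' @param model A [fit_confidence_model()] result.
#' @param path Output file.
#' @export
write_confidence_model <- function(model, path) {
  obj <- list(anchors = model$anchors, mu = model$mu, sigma = model$sigma,
              uniform_lo = model$uniform_lo, uniform_hi = model$uniform_hi,
              measures = model$measures, flagged = model$flagged,
              rho = model$rho)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_confidence_model
#' @export
read_confidence_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(anchors = obj$anchors,
                 mu = matrix(unlist(obj$mu), ncol = 4,
                             dimnames = list(NULL, obj$measures)),
                 sigma = matrix(unlist(obj$sigma), ncol = 4,
                                dimnames = list(NULL, obj$measures)),
                 uniform_lo = setNames(unlist(obj$uniform_lo), obj$measures),
                 uniform_hi = setNames(unlist(obj$uniform_hi), obj$measures),
                 measures = obj$measures, flagged = obj$flagged,
                 rho = obj$rho %||% NA_real_),
            class = "confidence_model")
}

#' Write a dendrogram in Java TreeView CDT + GTR format
#'
#' @param dendrogram A [agglomerate()] result.
#' @param profile_matrix Numeric matrix of profile values (rows = leaves in
#'   the dendrogram's label order).
#' @param path Output path prefix; `.cdt` and `.gtr` are appended.
#' @return Invisibly, the two file paths.
#' @export
write_treeview <- function(dendrogram, profile_matrix, path) {
  K <- dendrogram$n_leaves
  labels <- dendrogram$labels
  ord <- dendrogram_leaf_order(dendrogram)
  # correlation-like score column for GTR: map merge scores to (0, 1]
  sc <- dendrogram$height
  gtr_score <- 1 - (sc - min(sc)) / max(diff(range(sc)), 1e-12)
  node_name <- function(k) {
    if (k < 0) sprintf("GENE%dX", -k) else sprintf("NODE%dX", k)
  }
  gtr <- data.frame(
    node = vapply(seq_len(K - 1), function(s) node_name(s), character(1)),
    left = vapply(dendrogram$merge[, 1], node_name, character(1)),
    right = vapply(dendrogram$merge[, 2], node_name, character(1)),
    score = signif(gtr_score, 6))
  gtr_path <- paste0(path, ".gtr")
  write.table(gtr, gtr_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  cdt_path <- paste0(path, ".cdt")
  nc <- ncol(profile_matrix)
  header <- c("GID", "UNIQID", "NAME", "GWEIGHT",
              colnames(profile_matrix) %||% sprintf("V%d", seq_len(nc)))
  con <- file(cdt_path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  writeLines(paste(c("EWEIGHT", "", "", "", rep("1", nc)), collapse = "\t"),
             con)
  for (i in ord) {
    row <- c(sprintf("GENE%dX", i), labels[i], labels[i], "1",
             signif(profile_matrix[i, ], 6))
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(c(cdt_path, gtr_path))
}
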