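# Dataset and model checkpoint I/O. Everything is plain text (CSV, JSON) or
# lossless PNG; write -> read -> write round trips are byte-identical.

#' Write a dataset to disk
#'
#' Tabular data become a single CSV (`f1..fk, label, sensitive`). Image data
#' become one lossless 16-bit grayscale PNG per sample plus a
#' `manifest.csv` (filename, label, sensitive) in `path`.
#'
#' @param data an `lsp_dataset`.
#' @param path CSV file path (tabular) or directory (image).
#' @return the path, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "lsp_dataset"))
  if (data$modality == "tabular") {
    df <- as.data.frame(data$x)
    names(df) <- paste0("f", seq_len(ncol(df)))
    df$label <- data$y
    df$sensitive <- data$s
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    sz <- data$image_size
    fn <- sprintf("img_%05d.png", seq_len(nrow(data$x)))
    for (i in seq_len(nrow(data$x)))
      png::writePNG(matrix(data$x[i, ], sz, sz), file.path(path, fn[i]),
                    dpi = NULL)
    utils::write.csv(data.frame(filename = fn, label = data$y,
                                sensitive = data$s),
                     file.path(path, "manifest.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param path CSV file (tabular) or directory containing PNGs and
#'   `manifest.csv` (image).
#' @return an `lsp_dataset`.
#' @export
read_dataset <- function(path) {
  if (dir.exists(path)) {
    man <- utils::read.csv(file.path(path, "manifest.csv"))
    imgs <- lapply(man$filename, function(f)
      as.vector(png::readPNG(file.path(path, f))))
    x <- do.call(rbind, imgs)
    new_dataset(x, man$label, man$sensitive, "image",
                image_size = as.integer(sqrt(ncol(x))))
  } else {
    df <- utils::read.csv(path)
    feat <- grep("^f[0-9]+$", names(df), value = TRUE)
    new_dataset(as.matrix(df[, feat, drop = FALSE]), df$label, df$sensitive,
                "tabular")
  }
}

## ---- checkpoints -------------------------------------------------------------

.pack_net <- function(net) {
  list(role = net$role,
       layers = lapply(net$layers, function(l) {
         keep <- l[setdiff(names(l), c("geom", "params"))]
         keep$params <- lapply(l$params, function(p)
           list(dim = if (is.null(dim(p))) length(p) else dim(p),
                values = as.vector(p)))
         if (l$type %in% c("conv", "tconv"))
           keep$geom_args <- l$geom[c("H", "W", "C", "k", "stride", "pad")]
         keep
       }))
}

.unpack_net <- function(pk) {
  layers <- lapply(pk$layers, function(l) {
    l$params <- lapply(l$params, function(p) {
      v <- as.numeric(p$values)
      if (length(p$dim) > 1L) dim(v) <- unlist(p$dim)
      v
    })
    if (!is.null(l$geom_args)) {
      g <- l$geom_args
      l$geom <- conv_geometry(g$H, g$W, g$C, g$k, g$stride, g$pad)
      l$geom_args <- NULL
    }
    l
  })
  net <- list(layers = layers)
  net$role <- pk$role
  class(net) <- "lsp_network"
  net
}

#' Save a fitted LSP model as a JSON checkpoint
#'
#' The checkpoint stores the architecture spec, training configuration,
#' all network parameters (full double precision), batch-norm running
#' statistics, latent statistics and the training history in a single
#' version-tagged JSON file. Saving, loading and saving again produces
#' byte-identical files.
#'
#' @param model a fitted [lsp()] object.
#' @param path output file.
#' @return the path, invisibly.
#' @export
save_lsp <- function(model, path) {
  stopifnot(inherits(model, "lsp"))
  ck <- list(
    format = "lsproj-checkpoint",
    version = 1L,
    spec = unclass(model$spec),
    config = unclass(model$config),
    encoder = .pack_net(model$encoder),
    decoder = .pack_net(model$decoder),
    aux = if (!is.null(model$aux)) .pack_net(model$aux),
    discriminator = .pack_net(model$discriminator),
    latent_stats = list(mean_z_s = model$latent_stats$mean_z_s,
                        bank = model$latent_stats$bank),
    history = as.data.frame(unclass(model$history))[,
      c("epoch", "recon_loss", "disc_loss", "adv_loss", "routing_loss")],
    n_train = model$n_train)
  jsonlite::write_json(ck, path, digits = NA, auto_unbox = FALSE,
                       dataframe = "columns", matrix = "rowmajor",
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' Load an LSP model checkpoint
#'
#' @param path file written by [save_lsp()].
#' @return an object of class `lsp`.
#' @export
load_lsp <- function(path) {
  ck <- jsonlite::read_json(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  if (!identical(ck$format, "lsproj-checkpoint"))
    stop("not an lsproj checkpoint: ", path)
  spec <- ck$spec
  class(spec) <- "lsp_spec"
  config <- ck$config
  class(config) <- "lsp_train_config"
  hist <- as.data.frame(ck$history)
  class(hist) <- c("lsp_history", "data.frame")
  attr(hist, "final_recon") <- hist$recon_loss[nrow(hist)]
  obj <- list(encoder = .unpack_net(ck$encoder),
              decoder = .unpack_net(ck$decoder),
              aux = if (!is.null(ck$aux)) .unpack_net(ck$aux),
              spec = spec,
              discriminator = .unpack_net(ck$discriminator),
              config = config,
              history = hist,
              latent_stats = list(
                mean_z_s = as.numeric(ck$latent_stats$mean_z_s),
                bank = {
                  bk <- ck$latent_stats$bank
                  if (is.null(dim(bk))) dim(bk) <- c(1L, length(bk))
                  bk
                }),
              n_train = as.integer(ck$n_train))
  class(obj) <- "lsp"
  obj
}
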