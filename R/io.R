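#' Read an ordinal dataset from delimited text files
#'
#' The feature file is CSV or TSV (by extension: .tsv/.txt tab, otherwise
#' comma) with a header row of feature ids and a first column of sample
#' ids. The response file has two columns: sample id, ordinal label.
#' Responses are matched to feature rows by sample id, and labels are mapped
#' to 1..K through the explicit `levels` ordering (lowest first).
#'
#' @param xFile path to the feature matrix file.
#' @param yFile path to the two-column response file.
#' @param levels ordered category labels, lowest first.
#' @param standardize standardize columns after reading (default FALSE).
#' @return an [OrdinalDataset-class].
#' @export
readOrdinalDataset <- function(xFile, yFile, levels, standardize = FALSE) {
  sepOf <- function(f) if (grepl("\\.(tsv|txt)$", f, ignore.case = TRUE)) "\t" else ","
  xt <- utils::read.table(xFile, header = TRUE, sep = sepOf(xFile),
                          row.names = 1L, check.names = FALSE)
  yt <- utils::read.table(yFile, header = TRUE, sep = sepOf(yFile),
                          colClasses = "character")
  if (ncol(yt) < 2L) stop("response file must have sample id and label columns")
  idx <- match(rownames(xt), yt[[1L]])
  if (anyNA(idx)) stop("samples missing from the response file: ",
                       paste(rownames(xt)[is.na(idx)], collapse = ", "))
  ordinalDataset(as.matrix(xt), yt[[2L]][idx], levels = levels,
                 featureIds = colnames(xt), standardize = standardize)
}

#' Write an ordinal dataset to delimited text files
#'
#' @param data an [OrdinalDataset-class].
#' @param xFile,yFile output paths (CSV).
#' @return invisibly, the two paths.
#' @export
writeOrdinalDataset <- function(data, xFile, yFile) {
  X <- data@X
  rownames(X) <- sprintf("sample%04d", seq_len(nrow(X)))
  colnames(X) <- data@featureIds
  utils::write.csv(X, xFile)
  utils::write.csv(
    data.frame(sample_id = rownames(X), label = data@levels[data@y]),
    yFile, row.names = FALSE)
  invisible(c(xFile, yFile))
}

#' Read a prior/level configuration from YAML or JSON
#'
#' Recognized fields: `model`, `a`, `b`, `sigma2Alpha`, `sigma2_0`,
#' `sigma2_1`, `lambda0`, `piMode`, `t`, `c`, `d` (all optional except
#' `model`), plus an optional `levels` vector giving the response ordering.
#'
#' @param file path to a .yaml/.yml or .json file.
#' @return list with `prior` (a [PriorSpec-class]) and `levels`
#'   (character or NULL).
#' @export
readPriorConfig <- function(file) {
  cfg <- if (grepl("\\.ya?ml$", file, ignore.case = TRUE))
    yaml::read_yaml(file) else jsonlite::read_json(file, simplifyVector = TRUE)
  levels <- cfg$levels
  cfg$levels <- NULL
  known <- names(formals(priorSpec))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  prior <- do.call(priorSpec, cfg)
  list(prior = prior, levels = levels)
}

#' Write posterior draws as a directory of delimited arrays
#'
#' Each parameter block is written as a CSV with a chain column and one row
#' per saved iteration; `manifest.json` records shapes, the model variant,
#' prior and MCMC settings so the directory can be re-imported with
#' [readPosteriorDir()].
#'
#' @param samples a [PosteriorSamples-class].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
writePosteriorDir <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeArr <- function(arr, name, ids) {
    d <- dim(arr)
    if (length(d) == 2L) { arr <- array(arr, c(d, 1L)); d <- dim(arr) }
    flat <- do.call(rbind, lapply(seq_len(d[1L]), function(ch)
      cbind(chain = ch, iteration = seq_len(d[2L]),
            matrix(arr[ch, , ], d[2L], d[3L],
                   dimnames = list(NULL, ids)))))
    utils::write.csv(as.data.frame(flat), file.path(dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  Km1 <- dim(samples@alpha)[3L]
  writeArr(samples@alpha, "alpha", paste0("alpha", seq_len(Km1)))
  writeArr(samples@beta, "beta", samples@featureIds)
  if (!is.null(samples@gamma)) writeArr(samples@gamma, "gamma", samples@featureIds)
  if (!is.null(samples@pi)) writeArr(samples@pi, "pi", samples@featureIds)
  if (!is.null(samples@lambda)) writeArr(samples@lambda, "lambda", "lambda")
  pr <- samples@prior; ct <- samples@control
  manifest <- list(
    model = samples@model, featureIds = samples@featureIds,
    nChains = dim(samples@beta)[1L], nSavedPerChain = dim(samples@beta)[2L],
    K = Km1 + 1L,
    prior = list(model = pr@model, a = pr@a, b = pr@b,
                 sigma2Alpha = pr@sigma2Alpha, sigma2_0 = pr@sigma2_0,
                 sigma2_1 = pr@sigma2_1, lambda0 = pr@lambda0,
                 piMode = pr@piMode, t = pr@t, c = pr@c, d = pr@d),
    control = list(nChains = ct@nChains, nBurnin = ct@nBurnin,
                   nAdapt = ct@nAdapt, thin = ct@thin,
                   nSavedTotal = ct@nSavedTotal, seed = ct@seed))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read posterior draws written by [writePosteriorDir()]
#'
#' @param dir directory containing the per-parameter CSVs and manifest.
#' @return a [PosteriorSamples-class].
#' @export
readPosteriorDir <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  readArr <- function(name) {
    f <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(f)) return(NULL)
    tab <- utils::read.csv(f, check.names = FALSE)
    chains <- sort(unique(tab$chain))
    d3 <- ncol(tab) - 2L
    arr <- array(0, c(length(chains), manifest$nSavedPerChain, d3))
    for (ch in chains)
      arr[ch, , ] <- as.matrix(tab[tab$chain == ch, -(1:2), drop = FALSE])
    arr
  }
  pr <- manifest$prior
  prior <- priorSpec(pr$model, a = pr$a, b = pr$b,
                     sigma2Alpha = pr$sigma2Alpha, sigma2_0 = pr$sigma2_0,
                     sigma2_1 = pr$sigma2_1, lambda0 = pr$lambda0,
                     piMode = pr$piMode, t = pr$t, c = pr$c, d = pr$d)
  ct <- manifest$control
  control <- mcmcControl(ct$nChains, ct$nBurnin, ct$nAdapt, ct$thin,
                         ct$nSavedTotal, ct$seed)
  lam <- readArr("lambda")
  if (!is.null(lam)) lam <- array(lam, dim(lam)[1:2])
  new("PosteriorSamples", model = manifest$model, alpha = readArr("alpha"),
      beta = readArr("beta"), gamma = readArr("gamma"), pi = readArr("pi"),
      lambda = lam, featureIds = manifest$featureIds, prior = prior,
      control = control)
}
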