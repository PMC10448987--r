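#' Model specification for the guided autoencoder
#'
#' The embedding network is a fully connected autoencoder: an encoder
#' \eqn{f_\phi: R^D \to R^d} with SELU activations, mirrored by a decoder
#' \eqn{f_\theta: R^d \to R^D} whose output layer is linear. Two
#' single-layer heads read the latent code z: a batch predictor (softmax
#' over K batches; logistic when K = 2) and an optional biological-class
#' predictor. The joint loss per mini-batch of s cells is
#' \deqn{\sum_{i=1}^{s} [\lambda_1 \|x_i - \hat x_i\|^2
#'   - \lambda_2 \sum_k 1\{b_i = k\} \log B_{k,i}
#'   - \lambda_3 \sum_k 1\{y_i = k\} \log Y_{k,i}] + c \sum_w \|w\|^2}
#' with the L2 penalty (coefficient \code{l2Coeff}, default 1e-4) applied to
#' weights only, once per mini-batch.
#'
#' @param inputDim number of input features D.
#' @param encoderHidden integer vector of encoder hidden sizes
#'   (default \code{c(200, 100)}); the decoder mirrors it.
#' @param latentDim embedding dimension d (default 50; must be < D).
#' @param hiddenDropout dropout rate on hidden layers (default 0.15).
#' @param inputDropout dropout rate on the input layer (default 0; the
#'   high-dimensional variant uses 0.70).
#' @param l2Coeff L2 weight-decay coefficient (default 1e-4).
#' @param lambdas numeric(3): weights for reconstruction, batch
#'   cross-entropy, and biological cross-entropy. \code{lambdas[2] > 0}
#'   always (the batch head is the point of the method);
#'   \code{lambdas[3] = 0} exactly when biological labels are absent.
#' @return a list of class \code{"beeneModelSpec"}.
#' @export
beeneModelSpec <- function(inputDim,
                           encoderHidden = c(200L, 100L),
                           latentDim = 50L,
                           hiddenDropout = 0.15,
                           inputDropout = 0,
                           l2Coeff = 1e-4,
                           lambdas = c(1, 2, 1)) {
  inputDim <- as.integer(inputDim)
  latentDim <- as.integer(latentDim)
  stopifnot(inputDim > 0, latentDim > 0, length(lambdas) == 3L,
            all(lambdas >= 0), hiddenDropout >= 0, hiddenDropout < 1,
            inputDropout >= 0, inputDropout < 1, l2Coeff >= 0)
  if (latentDim >= inputDim)
    stop("latentDim must be smaller than inputDim")
  if (lambdas[2] <= 0)
    stop("lambda2 (batch head weight) must be positive")
  structure(list(inputDim = inputDim,
                 encoderHidden = as.integer(encoderHidden),
                 latentDim = latentDim,
                 decoderHidden = rev(as.integer(encoderHidden)),
                 activation = "selu",
                 hiddenDropout = hiddenDropout,
                 inputDropout = inputDropout,
                 l2Coeff = l2Coeff,
                 lambdas = as.numeric(lambdas)),
            class = "beeneModelSpec")
}

#' Named hyperparameter regimes
#'
#' Four ready-made regimes: \code{"default"} (lambdas (1, 2, 1), encoder
#' 200-100, 50-d latent) for labeled data; \code{"no_bio"} (lambdas
#' (1, 1, 0), bio head removed) when no biological variable exists;
#' \code{"high_dim"} (70\% input dropout, lambda1 = 0.001, lambda2 = 5.0)
#' for very wide matrices such as ~11k-gene data, where the reconstruction
#' MSE would otherwise swamp the cross-entropy terms; and \code{"pc_input"}
#' (single 50-neuron hidden layer, 20-d latent) for inputs that are already
#' principal-component scores.
#'
#' @param variant one of \code{"default"}, \code{"no_bio"},
#'   \code{"high_dim"}, \code{"pc_input"}.
#' @param inputDim number of input features.
#' @param ... overrides forwarded to \code{\link{beeneModelSpec}}.
#' @return a \code{"beeneModelSpec"}.
#' @export
beeneVariantSpec <- function(variant = c("default", "no_bio", "high_dim",
                                         "pc_input"),
                             inputDim, ...) {
  variant <- match.arg(variant)
  args <- switch(variant,
    default = list(lambdas = c(1, 2, 1)),
    no_bio = list(lambdas = c(1, 1, 0)),
    high_dim = list(lambdas = c(0.001, 5.0, 0), inputDropout = 0.70),
    pc_input = list(encoderHidden = 50L, latentDim = 20L,
                    lambdas = c(1, 2, 1)))
  over <- list(...)
  args[names(over)] <- over
  spec <- do.call(beeneModelSpec, c(list(inputDim = inputDim), args))
  spec$variant <- variant
  spec
}

#' Training configuration
#'
#' @param batchSize mini-batch size s (default 64).
#' @param maxEpochs maximum epochs (default 150).
#' @param patience early-stopping patience on validation total loss
#'   (default 30; generous because per-epoch improvements of the
#'   reconstruction-dominated objective are small relative to epoch noise);
#'   the parameters from the best validation epoch are kept.
#' @param learningRate step size (default 1e-3).
#' @param optimizer \code{"adam"} (default) or \code{"sgd"}.
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout; the same seed and data give an identical fit.
#' @param precision \code{"single"} (default; standard for this model
#'   family and about twice as fast) or \code{"double"}.
#' @return a list of class \code{"beeneTrainConfig"}.
#' @export
trainConfig <- function(batchSize = 64L, maxEpochs = 150L, patience = 30L,
                        learningRate = 1e-3,
                        optimizer = c("adam", "sgd"), seed = 1L,
                        precision = c("single", "double")) {
  optimizer <- match.arg(optimizer)
  precision <- match.arg(precision)
  stopifnot(batchSize >= 1, maxEpochs >= 1, patience >= 1, learningRate > 0)
  structure(list(batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs),
                 patience = as.integer(patience),
                 learningRate = learningRate,
                 optimizer = optimizer,
                 seed = as.integer(seed),
                 precision = precision),
            class = "beeneTrainConfig")
}

# Assemble C++ call inputs from a split + spec; shared by train and loss.
.modelSizes <- function(spec) {
  list(enc = c(spec$inputDim, spec$encoderHidden, spec$latentDim),
       dec = c(spec$latentDim, spec$decoderHidden, spec$inputDim))
}

#' Train the guided autoencoder
#'
#' Jointly optimizes encoder, decoder and prediction heads by mini-batch
#' gradient descent on the joint loss, monitoring the total validation loss
#' each epoch and restoring the parameters of the best validation epoch
#' (early stopping). Dropout is active during training only.
#'
#' @param split a \linkS4class{BeeneSplit} (standardize first with
#'   \code{\link{standardizeGenes}} for stable reconstruction scales).
#' @param spec a \code{"beeneModelSpec"}, or \code{NULL} to build one from
#'   \code{variant}.
#' @param variant regime name used when \code{spec} is NULL; see
#'   \code{\link{beeneVariantSpec}}.
#' @param config a \code{"beeneTrainConfig"}.
#' @return a \linkS4class{BeeneModel}.
#' @export
trainBeene <- function(split, spec = NULL, variant = "default",
                       config = trainConfig()) {
  train <- split@train
  val <- split@val
  K <- nBatches(train)
  if (K < 2L) stop("training data must carry >= 2 batches")
  M <- nBioClasses(train)
  if (is.null(spec)) {
    if (M == 0L && identical(variant, "default")) variant <- "no_bio"
    spec <- beeneVariantSpec(variant, inputDim = nrow(train))
  }
  if (spec$lambdas[3] > 0 && M < 2L)
    stop("lambda3 > 0 requires biological labels with >= 2 classes; ",
         "use the 'no_bio' variant or set lambdas[3] = 0")
  if (spec$lambdas[3] == 0) M <- 0L
  if (spec$inputDim != nrow(train))
    stop("spec$inputDim (", spec$inputDim, ") does not match the data (",
         nrow(train), " genes)")
  sizes <- .modelSizes(spec)
  params0 <- cpp_init_params(sizes$enc, sizes$dec, K, M, config$seed)
  ytr <- if (M >= 2L) bioCodes(train) else integer(0)
  yval <- if (M >= 2L) bioCodes(val) else integer(0)
  fit <- cpp_train(cellMatrix(train), batchCodes(train), ytr,
                   cellMatrix(val), batchCodes(val), yval,
                   params0,
                   spec$lambdas[1], spec$lambdas[2], spec$lambdas[3],
                   spec$l2Coeff,
                   spec$hiddenDropout, spec$inputDropout,
                   config$batchSize, config$maxEpochs, config$patience,
                   config$learningRate, config$optimizer, config$seed,
                   if (is.null(config$precision)) "single"
                   else config$precision)
  methods::new("BeeneModel",
               spec = unclass(spec),
               params = fit$params,
               trainLog = as.data.frame(fit$log),
               normStats = split@normStats,
               bestEpoch = as.integer(fit$best_epoch))
}

#' Encode cells into the latent embedding
#'
#' Deterministic inference pass (no dropout): row i of the result is
#' \eqn{f_\phi(x_i)}. Matrix input must already be on the scale the model
#' was trained on; a \linkS4class{BeeneExperiment} input is standardized
#' with the model's stored training statistics when available.
#'
#' @param model a \linkS4class{BeeneModel}.
#' @param x cells x genes matrix or a \linkS4class{BeeneExperiment}.
#' @param applyNormStats standardize \code{x} with the model's training
#'   statistics (default TRUE for BeeneExperiment input).
#' @return n x d embedding matrix with cell ids as rownames and attribute
#'   \code{source = "beene"}.
#' @export
encodeCells <- function(model, x, applyNormStats = TRUE) {
  if (methods::is(x, "BeeneExperiment")) {
    m <- cellMatrix(x)
    if (applyNormStats && length(model@normStats))
      m <- sweep(sweep(m, 2L, model@normStats$center), 2L,
                 model@normStats$scale, `/`)
  } else {
    m <- as.matrix(x)
  }
  if (ncol(m) != model@spec$inputDim)
    stop("input has ", ncol(m), " features; model expects ",
         model@spec$inputDim)
  z <- cpp_encode(m, model@params)
  rownames(z) <- rownames(m)
  attr(z, "source") <- "beene"
  z
}

#' Batch-head class probabilities
#'
#' For K >= 3 the head is a softmax regression on the latent code z,
#' \eqn{P(b = j | z) \propto \exp(\psi^{(j)\top} z)}; for K = 2 it is the
#' logistic regression \eqn{P(b = 1 | z) = \sigma(\psi^\top z)}. The two
#' parameterizations agree for K = 2 when the softmax weights are
#' \eqn{(0, \psi)}.
#'
#' @param z numeric vector (length d) or n x d matrix of latent codes.
#' @param psi weight vector (logistic, K = 2) or d x K matrix (softmax).
#' @param bias scalar (logistic) or length-K vector of head biases
#'   (default 0).
#' @return probability vector (or n x K matrix) summing to 1 per cell.
#' @export
batchHeadProbs <- function(z, psi, bias = NULL) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (any(!is.finite(z))) stop("latent code contains non-finite values")
  if (is.null(dim(psi)) || ncol(as.matrix(psi)) == 1L) {
    psi <- as.numeric(psi)
    if (is.null(bias)) bias <- 0
    u <- drop(z %*% psi) + bias
    p1 <- 1 / (1 + exp(-u))
    out <- cbind(`0` = 1 - p1, `1` = p1)
  } else {
    K <- ncol(psi)
    if (is.null(bias)) bias <- numeric(K)
    u <- sweep(z %*% psi, 2L, bias, `+`)
    u <- u - apply(u, 1L, max)
    e <- exp(u)
    out <- e / rowSums(e)
    colnames(out) <- as.character(seq_len(K) - 1L)
  }
  if (nrow(out) == 1L) drop(out) else out
}

#' Biological-head class probabilities
#'
#' Same contract as \code{\link{batchHeadProbs}} for the biological-class
#' head \eqn{\omega}.
#'
#' @param z latent code(s).
#' @param omega weight vector or d x M matrix; passing \code{NULL} (head
#'   disabled) is an error.
#' @param bias head bias (default 0).
#' @return probability vector (or matrix).
#' @export
bioHeadProbs <- function(z, omega, bias = NULL) {
  if (is.null(omega))
    stop("biological head is disabled (lambda3 = 0 / no bio labels)")
  batchHeadProbs(z, omega, bias)
}

#' Joint loss with per-term breakdown
#'
#' Evaluates the joint training objective (no dropout) on a set of cells
#' and returns the four components. The identity
#' \code{total == l1 * reconstruction + l2w * batchCE + l3 * bioCE +
#' l2Coeff * l2} holds to numerical precision; cross-entropies use a 1e-12
#' probability floor inside the log.
#'
#' @param x cells x genes matrix (model scale).
#' @param batch 0-based integer batch labels.
#' @param bio 0-based integer bio labels (or NULL).
#' @param model a \linkS4class{BeeneModel} (or a raw params list).
#' @param spec the model spec when \code{model} is a raw params list.
#' @return list with \code{total}, \code{reconstruction}, \code{batchCE},
#'   \code{bioCE}, \code{l2}.
#' @export
jointLoss <- function(x, batch, bio = NULL, model, spec = NULL) {
  if (methods::is(model, "BeeneModel")) {
    params <- model@params
    spec <- model@spec
  } else params <- model
  K <- params$K
  batch <- as.integer(batch)
  if (any(batch < 0 | batch >= K))
    stop("batch labels out of {0..K-1}")
  if (!is.null(bio) && params$M >= 2L) {
    bio <- as.integer(bio)
    if (any(bio < 0 | bio >= params$M))
      stop("bio labels out of {0..M-1}")
  } else bio <- integer(0)
  lp <- cpp_loss(as.matrix(x), batch, bio, params,
                 spec$lambdas[1], spec$lambdas[2], spec$lambdas[3],
                 spec$l2Coeff)
  list(total = lp$total, reconstruction = lp$reconstruction,
       batchCE = lp$batch_ce, bioCE = lp$bio_ce, l2 = lp$l2)
}
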