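# Shared fixtures, built in code at test time.

miClasses <- c("left_hand", "right_hand", "foot", "tongue")

# small fast recording with planted blinks for artifact tests
smallSim <- function(seed, nTrials = 8, nEEG = 8, nEOG = 1, ...) {
  montage <- defaultMontage(nEEG, nEOG)
  simulateRecording(montage = montage, nTrials = nTrials, seed = seed, ...)
}

# index of the SOBI component best matching the true blink source
blinkComponent <- function(dec, truth) {
  blink <- sourceSignals(truth)[truth@artifactSourceIndices[1], ]
  cors <- apply(sourceSignals(dec), 1, function(s) abs(cor(s, blink)))
  which.max(cors)
}

# brute-force dispersion entropy on an already-classified sequence:
# enumerate embedded vectors explicitly and count patterns in a list
dispEnOracle <- function(u, m = 2, d = 1) {
  nPat <- length(u) - (m - 1) * d
  pats <- character(nPat)
  for (i in seq_len(nPat))
    pats[i] <- paste(u[i + (0:(m - 1)) * d], collapse = "-")
  p <- table(pats) / nPat
  -sum(p * log(p))
}

# brute-force Sneddon Tsallis entropy: enumerate critical points of the
# successive-difference sign sequence and bin variances directly
sneddonOracle <- function(x) {
  n <- length(x)
  s <- sign(diff(x))
  cuts <- integer(0)
  last <- 0
  for (i in seq_along(s)) {
    if (s[i] == 0) cuts <- c(cuts, i + 1)
    else if (last != 0 && s[i] != last) cuts <- c(cuts, i)
    if (s[i] != 0) last <- s[i]
  }
  bounds <- sort(unique(c(0, cuts[cuts < n], n)))
  sigma2 <- mean((x - mean(x))^2)
  ratios <- sapply(seq_len(length(bounds) - 1), function(b) {
    seg <- x[(bounds[b] + 1):bounds[b + 1]]
    mean((seg - mean(seg))^2) / sigma2
  })
  1 - mean(ratios)
}

# feature table where class k shifts the columns of its own channel group
# (disjoint groups, mutually equidistant classes) — mirrors the generator's
# planted per-class channel structure
classFeatureTable <- function(seed, nPerClass = 15, effect = 2) {
  set.seed(seed)
  labs <- factor(rep(miClasses, each = nPerClass), levels = miClasses)
  cols <- as.vector(t(outer(paste0("C", 1:8),
                            c("FD", "Hur", "TsEn", "DispEn"), paste,
                            sep = ".")))
  M <- matrix(rnorm(length(labs) * 32), length(labs),
              dimnames = list(NULL, cols))
  for (k in 1:4) {
    rows <- which(as.integer(labs) == k)
    colIdx <- ((k - 1) * 8 + 1):(k * 8)  # channels 2k-1, 2k x 4 features
    M[rows, colIdx] <- M[rows, colIdx] + effect
  }
  new("FeatureTable", matrix = M, labels = labs, subjectId = "synthetic")
}

# two Gaussian clusters in 10-D separated along the first axis
twoClusters <- function(seed, n = 20, delta = 5) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n * 10), 2 * n)
  X[(n + 1):(2 * n), 1] <- X[(n + 1):(2 * n), 1] + delta
  X
}

# feature table with a planted class effect of size `effect` (in SDs) on
# half the channels, gaussian noise elsewhere
plantedFeatureTable <- function(seed, nPerClass = 10, nChan = 4,
                                effect = 1) {
  set.seed(seed)
  labs <- factor(rep(miClasses, each = nPerClass), levels = miClasses)
  cols <- as.vector(t(outer(paste0("C", seq_len(nChan)),
                            c("FD", "Hur", "TsEn", "DispEn"), paste,
                            sep = ".")))
  M <- matrix(rnorm(length(labs) * length(cols)), length(labs),
              dimnames = list(NULL, cols))
  shift <- effect * (as.integer(labs) - 2.5) / 2
  hurCols <- grep("\\.Hur$", cols)
  M[, hurCols] <- M[, hurCols] + shift
  new("FeatureTable", matrix = M, labels = labs, subjectId = "synthetic")
}
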