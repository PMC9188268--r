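# Whole-word hidden Markov models with single-Gaussian diagonal-covariance
# emissions, trained by segmental Baum-Welch, and Viterbi decoding under a
# slot-constrained matrix-sentence grammar
# (start . slot1 .. slot5 . end, each slot a parallel bank of word models).

#' HMM topology / training configuration
#'
#' @param states_word emitting states per word model
#' @param states_sil emitting states of the silence model
#' @param states_edge emitting states of the start and end models
#' @param var_floor diagonal-covariance floor
#' @param max_iter Baum-Welch iteration cap
#' @param tol relative log-likelihood convergence tolerance
#' @export
hmm_config <- function(states_word = 8L, states_sil = 6L,
                       states_edge = 3L, var_floor = 1e-3,
                       max_iter = 20L, tol = 1e-4) {
  structure(list(states_word = states_word, states_sil = states_sil,
                 states_edge = states_edge, var_floor = var_floor,
                 max_iter = max_iter, tol = tol),
            class = "hmm_config")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# per-state Gaussian log-likelihoods for all frames: T x S matrix
gauss_loglik <- function(X, mu, vr) {
  iv <- 1 / vr                                     # S x D
  c0 <- -0.5 * (ncol(X) * log(2 * pi) + rowSums(log(vr)) +
                  rowSums(mu^2 * iv))
  X2 <- X^2
  sweep(-0.5 * X2 %*% t(iv) + X %*% t(mu * iv), 2, c0, "+")
}

# flat-start initialization: uniform segmentation of every segment
hmm_init <- function(segs, n_states, var_floor) {
  D <- ncol(segs[[1]])
  acc_n <- numeric(n_states)
  acc_x <- matrix(0, n_states, D)
  acc_x2 <- matrix(0, n_states, D)
  for (seg in segs) {
    T_ <- nrow(seg)
    st <- pmin(ceiling(seq_len(T_) / T_ * n_states), n_states)
    for (s in seq_len(n_states)) {
      rows <- seg[st == s, , drop = FALSE]
      acc_n[s] <- acc_n[s] + nrow(rows)
      acc_x[s, ] <- acc_x[s, ] + colSums(rows)
      acc_x2[s, ] <- acc_x2[s, ] + colSums(rows^2)
    }
  }
  mu <- acc_x / pmax(acc_n, 1)
  vr <- pmax(acc_x2 / pmax(acc_n, 1) - mu^2, var_floor)
  list(n_states = n_states, mu = mu, var = vr,
       a_self = rep(0.5, n_states))
}

# elementwise log(exp(a) + exp(b)), -Inf-safe
lse2 <- function(a, b) {
  m <- pmax(a, b)
  fin <- is.finite(m)
  out <- m
  out[fin] <- m[fin] + log1p(exp(-abs(a - b)[fin]))
  out
}

# forward-backward in log space for one left-to-right chain (enter at
# state 1, exit from the last state).  Returns log-likelihood and
# accumulators.
fb_chain <- function(B, a_self) {
  T_ <- nrow(B); S <- ncol(B)
  la_self <- log(a_self)
  la_next <- log(1 - a_self)
  alpha <- matrix(-Inf, T_, S)
  alpha[1, 1] <- B[1, 1]
  for (t in 2:T_) {
    stay <- alpha[t - 1, ] + la_self
    move <- c(-Inf, alpha[t - 1, -S] + la_next[-S])
    alpha[t, ] <- lse2(stay, move) + B[t, ]
  }
  ll <- alpha[T_, S] + la_next[S]                 # exit from last state
  beta <- matrix(-Inf, T_, S)
  beta[T_, ] <- c(rep(-Inf, S - 1), la_next[S])
  for (t in (T_ - 1):1) {
    stay <- beta[t + 1, ] + la_self + B[t + 1, ]
    move <- c(beta[t + 1, -1] + la_next[-S] + B[t + 1, -1], -Inf)
    beta[t, ] <- lse2(stay, move)
  }
  gamma <- alpha + beta - ll
  gamma <- exp(gamma)
  # transition posteriors for self-loops
  xi_self <- sapply(seq_len(S), function(s) {
    if (T_ < 2) return(0)
    sum(exp(alpha[1:(T_ - 1), s] + la_self[s] + B[2:T_, s] +
              beta[2:T_, s] - ll))
  })
  list(ll = ll, gamma = gamma, xi_self = xi_self)
}

# Baum-Welch training of one chain on a list of segments
train_chain <- function(segs, n_states, cfg) {
  segs <- segs[vapply(segs, nrow, integer(1)) >= n_states]
  if (length(segs) == 0) stop("no segment long enough for ", n_states,
                              " states")
  mod <- hmm_init(segs, n_states, cfg$var_floor)
  ll_old <- -Inf
  for (it in seq_len(cfg$max_iter)) {
    D <- ncol(mod$mu)
    acc_g <- numeric(n_states)
    acc_x <- matrix(0, n_states, D)
    acc_x2 <- matrix(0, n_states, D)
    acc_self <- numeric(n_states)
    ll_tot <- 0
    for (seg in segs) {
      B <- gauss_loglik(seg, mod$mu, mod$var)
      fb <- fb_chain(B, mod$a_self)
      if (!is.finite(fb$ll)) next
      ll_tot <- ll_tot + fb$ll
      acc_g <- acc_g + colSums(fb$gamma)
      acc_x <- acc_x + t(fb$gamma) %*% seg
      acc_x2 <- acc_x2 + t(fb$gamma) %*% seg^2
      acc_self <- acc_self + fb$xi_self
    }
    mod$mu <- acc_x / pmax(acc_g, 1e-10)
    mod$var <- pmax(acc_x2 / pmax(acc_g, 1e-10) - mod$mu^2, cfg$var_floor)
    mod$a_self <- pmin(pmax(acc_self / pmax(acc_g, 1e-10), 1e-4), 1 - 1e-4)
    if (is.finite(ll_old) &&
        abs(ll_tot - ll_old) < cfg$tol * (abs(ll_old) + 1)) break
    ll_old <- ll_tot
  }
  mod
}

#' Train word, silence and edge HMMs from labelled sentence features
#'
#' Each training sentence provides a feature matrix plus its five word
#' labels and word frame intervals; every word model is trained on its
#' segments by Baum-Welch from a flat start.  Leading/trailing frames feed
#' the start, end and silence models.
#'
#' @param train_data list of sentences: each
#'   `list(features, words, frame_bounds)` where `frame_bounds` is a
#'   5-by-2 matrix of first/last frame per word
#' @param vocabulary the 5-slot vocabulary the models must cover
#' @param cfg an [hmm_config()]
#' @param seed accepted for interface symmetry; training is deterministic
#' @return object of class `hmm_models`
#' @export
train_models <- function(train_data, vocabulary, cfg = hmm_config(),
                         seed = 1) {
  all_words <- unlist(vocabulary)
  seen <- unlist(lapply(train_data, `[[`, "words"))
  missing <- setdiff(all_words, seen)
  if (length(missing) > 0)
    stop("no training data for word(s): ",
         paste(missing, collapse = ", "))
  word_segs <- new.env()
  edge_head <- list(); edge_tail <- list()
  for (sent in train_data) {
    fb <- sent$frame_bounds
    for (k in seq_len(5)) {
      w <- sent$words[k]
      rows <- sent$features[fb[k, 1]:fb[k, 2], , drop = FALSE]
      word_segs[[w]] <- c(word_segs[[w]], list(rows))
    }
    if (fb[1, 1] > 1)
      edge_head <- c(edge_head,
                     list(sent$features[1:(fb[1, 1] - 1), , drop = FALSE]))
    if (fb[5, 2] < nrow(sent$features))
      edge_tail <- c(edge_tail,
                     list(sent$features[(fb[5, 2] + 1):nrow(sent$features),
                                        , drop = FALSE]))
  }
  words <- stats::setNames(lapply(all_words, function(w)
    train_chain(word_segs[[w]], cfg$states_word, cfg)), all_words)
  sil_segs <- c(edge_head, edge_tail)
  edge_cfg <- cfg
  start_mod <- train_chain(if (length(edge_head)) edge_head else sil_segs,
                           cfg$states_edge, edge_cfg)
  end_mod <- train_chain(if (length(edge_tail)) edge_tail else sil_segs,
                         cfg$states_edge, edge_cfg)
  silence <- train_chain(sil_segs, cfg$states_sil, cfg)
  structure(list(words = words, start = start_mod, end = end_mod,
                 silence = silence, vocabulary = vocabulary, cfg = cfg),
            class = "hmm_models")
}

# --- grammar composition and Viterbi decoding -----------------------------

# builds the composed state space: start . slot1..slot5 . end
build_graph <- function(models) {
  segs <- c(list(list(start = models$start)),
            lapply(models$vocabulary, function(slot_words)
              models$words[slot_words]),
            list(list(end = models$end)))
  chains <- list(); seg_of <- integer(0); alt_of <- character(0)
  offset <- 0L
  seg_starts <- list(); seg_ends <- list()
  mu <- NULL; vr <- NULL; a_self <- numeric(0)
  chain_start <- logical(0); chain_end <- logical(0)
  for (gi in seq_along(segs)) {
    starts <- integer(0); ends <- integer(0)
    for (alt in names(segs[[gi]])) {
      mod <- segs[[gi]][[alt]]
      S <- mod$n_states
      idx <- offset + seq_len(S)
      starts <- c(starts, idx[1]); ends <- c(ends, idx[S])
      mu <- rbind(mu, mod$mu); vr <- rbind(vr, mod$var)
      a_self <- c(a_self, mod$a_self)
      cs <- rep(FALSE, S); cs[1] <- TRUE
      ce <- rep(FALSE, S); ce[S] <- TRUE
      chain_start <- c(chain_start, cs); chain_end <- c(chain_end, ce)
      seg_of <- c(seg_of, rep(gi, S))
      alt_of <- c(alt_of, rep(alt, S))
      offset <- offset + S
    }
    seg_starts[[gi]] <- starts; seg_ends[[gi]] <- ends
  }
  list(mu = mu, var = vr, a_self = a_self, chain_start = chain_start,
       chain_end = chain_end, seg_of = seg_of, alt_of = alt_of,
       seg_starts = seg_starts, seg_ends = seg_ends,
       n_states = length(a_self), n_segs = length(segs))
}

# Viterbi decode one sentence; returns the winning alternative per slot
viterbi_decode <- function(X, graph) {
  B <- gauss_loglik(X, graph$mu, graph$var)
  T_ <- nrow(B); S <- graph$n_states
  la_self <- log(graph$a_self); la_next <- log(1 - graph$a_self)
  delta <- rep(-Inf, S)
  delta[graph$seg_starts[[1]]] <- B[1, graph$seg_starts[[1]]]
  psi <- matrix(0L, T_, S)
  for (t in 2:T_) {
    stay <- delta + la_self
    move <- c(-Inf, (delta + la_next)[-S])
    move[graph$chain_start] <- -Inf
    # segment joins: best exit of the previous segment feeds chain starts
    enter <- rep(-Inf, S)
    enter_src <- rep(0L, S)
    for (gi in 2:graph$n_segs) {
      ends <- graph$seg_ends[[gi - 1]]
      sc <- (delta + la_next)[ends]
      bi <- which.max(sc)
      starts <- graph$seg_starts[[gi]]
      branch <- -log(length(starts))
      enter[starts] <- sc[bi] + branch
      enter_src[starts] <- ends[bi]
    }
    new_delta <- pmax(stay, move, enter)
    src <- ifelse(new_delta == stay, seq_len(S),
                  ifelse(new_delta == move, seq_len(S) - 1L, enter_src))
    psi[t, ] <- src
    delta <- new_delta + B[t, ]
  }
  # terminate at the end model's last state
  final <- graph$seg_ends[[graph$n_segs]][1]
  path <- integer(T_)
  path[T_] <- final
  for (t in T_:2) path[t - 1] <- psi[t, path[t]]
  words <- character(5)
  for (slot in seq_len(5)) {
    gi <- slot + 1L
    occ <- path[graph$seg_of[path] == gi]
    words[slot] <- if (length(occ)) graph$alt_of[occ[1]] else NA_character_
  }
  list(words = words, loglik = delta[final])
}

#' Recognize sentences under the slot-constrained grammar
#'
#' Maximum-likelihood Viterbi decoding of each sentence through
#' start - five word slots (parallel alternatives) - end, and word-correct
#' scoring against the true labels.
#'
#' @param test_data list of sentences `list(features, words)`
#' @param models an [train_models()] model set
#' @return list with `rate` (percent words correct), `per_sentence`
#'   decoded words
#' @export
recognize <- function(test_data, models) {
  graph <- build_graph(models)
  decoded <- lapply(test_data, function(sent)
    viterbi_decode(sent$features, graph)$words)
  n_corr <- sum(vapply(seq_along(test_data), function(i)
    sum(decoded[[i]] == test_data[[i]]$words, na.rm = TRUE), numeric(1)))
  list(rate = n_corr / (5 * length(test_data)) * 100,
       per_sentence = decoded)
}
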