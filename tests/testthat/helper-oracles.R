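# Independent oracles used to cross-check the package implementations.
# These are deliberately naive (loops, exhaustive enumeration) and share
# no code with the package internals.

# Literal walk of the GSEA-style running sum: hit adds |w|^p / sum_hits,
# miss subtracts 1/(N - N_hits); ES is the max |S|, earliest index.
running_sum_oracle <- function(membership, weights, p = 1) {
    N <- length(membership)
    n_hit <- sum(membership)
    wsum <- 0
    for (i in seq_len(N)) if (membership[i]) wsum <- wsum + abs(weights[i])^p
    S <- numeric(N)
    s <- 0
    for (i in seq_len(N)) {
        if (membership[i]) s <- s + abs(weights[i])^p / wsum
        else s <- s - 1 / (N - n_hit)
        S[i] <- s
    }
    peak <- 1L
    for (i in seq_len(N)) if (abs(S[i]) > abs(S[peak])) peak <- i
    list(S = S, es = S[peak], peak_index = peak)
}

# Literal BH step-up: q_(i) = min_{j >= i} m p_(j) / j, clipped to 1.
bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    sorted <- p[o]
    q_sorted <- numeric(m)
    for (i in seq_len(m)) {
        vals <- numeric(0)
        for (j in i:m) vals <- c(vals, m * sorted[j] / j)
        q_sorted[i] <- min(c(vals, 1))
    }
    q <- numeric(m)
    q[o] <- q_sorted
    q
}

# Mann-Whitney U by direct pairwise comparison (ties count 1/2) and the
# exact one-sided p by exhaustive enumeration of all label assignments.
mwu_oracle <- function(scores, in_class) {
    pair_u <- function(a, b) {
        u <- 0
        for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
        u
    }
    u_obs <- pair_u(scores[in_class], scores[!in_class])
    m <- sum(in_class)
    combos <- utils::combn(length(scores), m)
    us <- apply(combos, 2L, function(ix)
        pair_u(scores[ix], scores[-ix]))
    list(u = u_obs, p = mean(us >= u_obs))
}

# Superposition oracle via bio3d's least-squares fitting.
kabsch_rmsd_oracle <- function(X, Y) {
    fixed <- as.numeric(t(X))
    mobile <- as.numeric(t(Y))
    fitted <- bio3d::fit.xyz(fixed, mobile,
                             fixed.inds = seq_along(fixed),
                             mobile.inds = seq_along(mobile))
    fm <- matrix(fitted, ncol = 3, byrow = TRUE)
    sqrt(mean(rowSums((fm - X)^2)))
}

# All-pairs atom-distance site expansion: residue keys (resno, icode) of
# catalytic residues plus every residue with an atom within cutoff of a
# catalytic atom.
expand_oracle <- function(at, cat_resno, cutoff) {
    keys <- paste(at$resno, at$insert)
    cat_rows <- which(at$resno %in% cat_resno)
    hit <- rep(FALSE, nrow(at))
    for (i in seq_len(nrow(at))) {
        for (j in cat_rows) {
            d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                      (at$z[i] - at$z[j])^2)
            if (d <= cutoff) { hit[i] <- TRUE; break }
        }
    }
    sort(unique(c(keys[hit], keys[at$resno %in% cat_resno])))
}

# Toy atom table: standard residues, optional waters / ions / altlocs.
make_toy_protein <- function(n_res = 5L, seed = 1L, spacing = 4,
                             with_het = FALSE) {
    set.seed(seed)
    aas <- sitenrich::standardAminoAcids()
    rows <- list()
    for (r in seq_len(n_res)) {
        for (a in c("N", "CA", "C", "O")) {
            rows[[length(rows) + 1L]] <- data.frame(
                type = "ATOM", elety = a, elesy = substr(a, 1, 1),
                resid = aas[(r %% 20) + 1], chain = "A",
                resno = r, insert = "", alt = "",
                x = spacing * r + rnorm(1, sd = 0.3),
                y = rnorm(1, sd = 0.3), z = rnorm(1, sd = 0.3),
                b = 90, stringsAsFactors = FALSE)
        }
    }
    at <- do.call(rbind, rows)
    if (with_het) {
        het <- data.frame(
            type = "HETATM", elety = c("O", "O", "ZN"),
            elesy = c("O", "O", "ZN"), resid = c("HOH", "HOH", "ZN"),
            chain = "A", resno = c(101L, 102L, 103L), insert = "",
            alt = "", x = c(50, 51, 52), y = 0, z = 0, b = 20,
            stringsAsFactors = FALSE)
        at <- rbind(at, het)
    }
    at
}

# Random abstract embedding fixtures shared across test files.
toy_spec <- function(...) sitenrich::syntheticSpec(seed = 11L, ...)
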