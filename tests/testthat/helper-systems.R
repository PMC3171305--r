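# small systems built in code for tests

# pure birth 0 -> B at rate c, absorbing at x0 + 1: closed form 1 - exp(-c*T)
birth_toy <- function(c = 0.02) {
  reaction_system("B", 0, list(reaction(NULL, c(B = 1), rate = c)),
                  name = "birth_toy")
}

# dimer birth-death toy: 0 -> 2B (rate c1), B -> 0 (rate c2)
dimer_toy <- function(c1 = 0.5, c2 = 0.05) {
  reaction_system("B", 10,
                  list(reaction(NULL, c(B = 2), rate = c1),
                       reaction(c(B = 1), NULL, rate = c2)),
                  name = "dimer_toy")
}

fixture_event <- function(name, theta, ...) {
  fx <- fixture_system(name)
  list(system = fx$system,
       event = rare_event(fx$system, fx$target, theta = theta,
                          horizon = fx$horizon, ...))
}

# brute-force argmax of the dominant-term profile over a fine grid
brute_two_group_Q1 <- function(K_E, eta, grid = seq(1e-4, 1 - 1e-4, 1e-4)) {
  eta <- abs(eta)
  K1 <- (K_E + eta) / 2
  K2 <- K_E - K1
  obj <- K1 * log(grid) + K2 * log(1 - grid)
  grid[which.max(obj)]
}

brute_kappa <- function(K_E, eta, Q_hat) {
  eta <- abs(eta)
  K2 <- 0:floor((K_E - eta) / 2)
  K1 <- K2 + eta
  K3 <- K_E - 2 * K2 - eta
  lt <- lgamma(K_E + 1) - lgamma(K1 + 1) - lgamma(K2 + 1) - lgamma(K3 + 1)
  for (i in 1:3) {
    k <- list(K1, K2, K3)[[i]]
    lt <- lt + ifelse(k > 0, k * log(Q_hat[i]), 0)
  }
  K2[which.max(lt)]
}
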