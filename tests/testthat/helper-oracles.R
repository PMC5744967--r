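# Independent oracles shared across test files.

# Pseudoinverse least-squares oracle: predictions of the minimum-norm
# least-squares fit on the column space of centred X.
pinv_predictions <- function(X, y, Xnew = X) {
  xc <- colMeans(X)
  Xc <- sweep(X, 2, xc)
  beta <- MASS::ginv(Xc) %*% (y - mean(y))
  drop(sweep(Xnew, 2, xc) %*% beta + mean(y))
}

# Independent second transcription of every index formula, written directly
# from the published comparison table as plain functions of rho(lambda).
# Guards the shipped registry against transcription typos.
oracle_indices <- function(rho) {
  list(
    SR1 = rho(750) / rho(700),
    DoubleDifference = (rho(749) - rho(720)) - (rho(701) - rho(672)),
    Vogelmann1 = rho(740) / rho(720),
    mSR705 = (rho(750) - rho(445)) / (rho(705) - rho(445)),
    SRCarter = rho(760) / rho(695),
    Maccioni = (rho(780) - rho(710)) / (rho(780) - rho(680)),
    SR3 = rho(750) / rho(550),
    Gitelson = 1 / rho(700),
    Datt4 = rho(672) / (rho(550) * rho(708)),
    SR4 = rho(700) / rho(670),
    SR2 = rho(752) / rho(690),
    NDVI = (rho(860) - rho(690)) / (rho(860) + rho(690)),
    Vogelmann2 = (rho(734) - rho(747)) - (rho(715) + rho(726)),
    mNDVI = (rho(800) - rho(680)) / (rho(800) + rho(680) - 2 * rho(445)),
    NDWI = (rho(860) - rho(1240)) / (rho(860) + rho(1240)),
    SIPI = rho(800) - rho(445),
    PRI = (rho(531) - rho(570)) / (rho(531) + rho(570)),
    mSRCHL = (rho(800) - rho(445)) / (rho(680) - rho(445))
  )
}
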