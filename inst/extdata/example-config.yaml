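# Example run configuration for glottochron::run_inference().
#
# All ages are in ka BP (thousands of years before present). The data file
# here is SYNTHETIC (produced by write_simulation() from the bundled
# generator); replace `data`, `tip_dates`, `calibrations` and `constraints`
# with your own curated values -- calibration dates are always user-supplied.

data: cognates.csv          # CSV dialect: language,concept,cognate_class,is_loan
data_format: csv

exclude_taxa: []            # e.g. heavily borrowing or duplicated varieties

# last-seen ages of historically attested languages (extant tips omitted)
tip_dates:
  Lx1: 1.10
  Lx2: 0.45

model:
  kind: m1p+CV              # m1p | m1p+G4 | m1p+CV
  gain: 1.0                 # initial values; all rates are sampled
  loss: 1.0
  s_on: 0.5
  s_off: 0.5
  normalize: true           # unit expected visible substitution rate
  ascertainment: false

clock:
  kind: relaxed-lognormal   # strict | relaxed-lognormal
  rate: 0.3                 # substitutions per cognate set per ka (initial)
  mu: 1.0                   # real-space mean of branch multipliers
  sigma: 0.1                # log-space sd of branch multipliers

fbd:
  lambda: 0.5               # language birth rate per ka (initial)
  mu: 0.05                  # death rate
  psi: 0.1                  # through-time sampling rate (extinct tips)
  rho: 0.8                  # extant sampling proportion (Uniform[0,1] prior)

priors:
  mean_gain: 10             # exponential prior means
  mean_loss: 10
  mean_clock_rate: 1
  mean_lambda: 1
  mean_mu: 1
  mean_psi: 1

calibrations:
  - type: tip_date          # pins an extinct tip to its last-seen date
    taxon: Lx1
    age_ka: 1.10
  - type: tip_date
    taxon: Lx2
    age_ka: 0.45
  - type: mrca_min_age      # hard lower bound on a clade's MRCA age
    taxa: [L1, L2, L3]
    min_age_ka: 1.5

constraints:
  - taxa: [L1, L2]          # required clade ...
    outgroup: true          # ... forming one side of the root split

mcmc:
  chain_length: 200000
  burn_in: 40000
  sample_every: 160
  n_chains: 2
  seed: 1

output_dir: out
seed: 1
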