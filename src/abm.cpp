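// Agent-based evolutionary simulation on the complete territorial-raider
// graph, plus a bulk sampler for placement configurations. The per-replicate
// RNG is a counter-seeded xoshiro256++ stream so replicates are
// order-independent and runs are reproducible from the master seed alone.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  inline int randint(int n) { // uniform on 0..n-1
    int v = (int)(unif() * n);
    return v >= n ? n - 1 : v;
  }
};

// One simultaneous movement event. place[i] receives the 0-based place of
// individual i. Mechanism codes: 1 independent, 2 follow-the-majority,
// 3 polya-urn, 4 wheel. t is the quantized spike step theta/(2*pi).
static void move_all(Xoshiro &rng, int mech, double h, int N, double B,
                     double t, std::vector<int> &place,
                     std::vector<int> &parts, std::vector<double> &wts) {
  const int M = N;
  const double denom = h + M - 1.0;
  double pm;
  if (h > 1.0) pm = M / denom;
  else if (h == 1.0) pm = 1.0;
  else pm = M * h / denom;
  int np = 0;
  for (int i = 0; i < N; ++i) {
    double u = rng.unif();
    if (u < pm) {
      parts[np++] = i;
    } else if (h > 1.0) {
      place[i] = i; // stay home
    } else {
      int m = rng.randint(M - 1); // uniform non-home place
      if (m >= i) ++m;
      place[i] = m;
    }
  }
  if (np == 0) return;
  if (mech == 2 || (mech == 3 && B == 0.0)) {
    // follow-the-majority: a single cluster at a uniform place
    int m = rng.randint(M);
    for (int j = 0; j < np; ++j) place[parts[j]] = m;
  } else if (mech == 1) {
    for (int j = 0; j < np; ++j) place[parts[j]] = rng.randint(M);
  } else if (mech == 3) {
    // urn weights B/M + occupancy; draws are exchangeable so participant
    // index order is a valid sequential order
    for (int m = 0; m < M; ++m) wts[m] = B / M;
    double total = B;
    for (int j = 0; j < np; ++j) {
      double u = rng.unif() * total;
      int m = 0;
      double acc = wts[0];
      while (u >= acc && m < M - 1) { ++m; acc += wts[m]; }
      place[parts[j]] = m;
      wts[m] += 1.0;
      total += 1.0;
    }
  } else {
    // wheel: shuffle spike-to-participant assignment, spin once
    for (int j = np - 1; j > 0; --j) {
      int r = rng.randint(j + 1);
      int tmp = parts[j]; parts[j] = parts[r]; parts[r] = tmp;
    }
    double phi = rng.unif();
    for (int j = 0; j < np; ++j) {
      double pos = phi + j * t;
      pos -= std::floor(pos);
      int m = (int)(pos * M);
      if (m >= M) m = M - 1;
      place[parts[j]] = m;
    }
  }
}

// payoff of one individual given its role (1 = A, 0 = B) and the group
// composition (a of type A, b of type B, a + b >= 1)
static inline double payoff(int game, double R, double V, double C,
                            int isA, int a, int b) {
  int n = a + b;
  if (game == 1) { // public goods: A cooperates
    if (isA) {
      return a == 1 ? R - C : R - C + ((double)(a - 1) / (n - 1)) * V;
    }
    return a == 0 ? R : R + ((double)a / (n - 1)) * V;
  }
  // hawk-dove: A is the hawk
  if (isA) return R + (V - (a - 1.0) * C) / a;
  return a > 0 ? R : R + V / b;
}

// [[Rcpp::export]]
List abm_estimate_cpp(int mech, double h, int N, double B, double t,
                      int game, double R, double V, double C,
                      int dynamics, int mutant_is_A, int replicates,
                      double seed, double max_steps,
                      bool bdb_include_parent, bool idealized,
                      NumericVector fit_mutant_tab,
                      NumericVector fit_resident_tab) {
  IntegerVector outcome(replicates);
  NumericVector steps_out(replicates);
  const uint64_t base = (uint64_t)seed;
  std::vector<int> place(N), place2(N), parts(N), type(N), members(N);
  std::vector<double> wts(N), fit(N), cum(N);
  std::vector<int> cntA(N), cnt(N);

  for (int rep = 0; rep < replicates; ++rep) {
    uint64_t mix = base ^ (0x9E3779B97F4A7C15ULL * (uint64_t)(rep + 1));
    Xoshiro rng(mix);
    for (int i = 0; i < N; ++i) type[i] = 0;
    type[rng.randint(N)] = 1; // mutant on a random vertex
    int k = 1;
    double steps = 0;
    int res = -1;
    while (steps < max_steps) {
      steps += 1;
      // (i) movement + one round of games -> realized fitness
      if (idealized) {
        for (int i = 0; i < N; ++i) {
          fit[i] = type[i] ? fit_mutant_tab[k - 1] : fit_resident_tab[k - 1];
        }
      } else {
        move_all(rng, mech, h, N, B, t, place, parts, wts);
        for (int m = 0; m < N; ++m) { cntA[m] = 0; cnt[m] = 0; }
        for (int i = 0; i < N; ++i) {
          ++cnt[place[i]];
          int isA = (type[i] == 1) == (mutant_is_A == 1);
          if (isA) ++cntA[place[i]];
        }
        for (int i = 0; i < N; ++i) {
          int m = place[i];
          int isA = (type[i] == 1) == (mutant_is_A == 1);
          fit[i] = payoff(game, R, V, C, isA, cntA[m], cnt[m] - cntA[m]);
        }
      }
      // (ii) return home; (iii) fresh movement, no game
      move_all(rng, mech, h, N, B, t, place2, parts, wts);
      // (iv) reproduction and replacement
      int repro;
      if (dynamics == 1) { // BDB: reproducer proportional to fitness
        double tot = 0;
        for (int i = 0; i < N; ++i) { tot += fit[i]; cum[i] = tot; }
        double u = rng.unif() * tot;
        repro = 0;
        while (u >= cum[repro] && repro < N - 1) ++repro;
      } else {
        repro = rng.randint(N);
      }
      int victim = repro;
      int nm = 0;
      int pm_ = place2[repro];
      for (int i = 0; i < N; ++i) {
        if (place2[i] == pm_ && (i != repro || bdb_include_parent))
          members[nm++] = i;
      }
      if (dynamics == 1) {
        if (nm > 0) victim = members[rng.randint(nm)];
      } else { // BDD: victim proportional to inverse fitness among co-members
        // parent excluded unless alone
        nm = 0;
        for (int i = 0; i < N; ++i) {
          if (place2[i] == pm_ && i != repro) members[nm++] = i;
        }
        if (nm > 0) {
          double tot = 0;
          for (int j = 0; j < nm; ++j) { tot += 1.0 / fit[members[j]]; cum[j] = tot; }
          double u = rng.unif() * tot;
          int j = 0;
          while (u >= cum[j] && j < nm - 1) ++j;
          victim = members[j];
        }
      }
      if (type[victim] != type[repro]) {
        k += type[repro] == 1 ? 1 : -1;
        type[victim] = type[repro];
        if (k == 0) { res = 0; break; }
        if (k == N) { res = 1; break; }
      }
    }
    outcome[rep] = res;
    steps_out[rep] = steps;
  }
  return List::create(_["outcome"] = outcome, _["steps"] = steps_out);
}

// [[Rcpp::export]]
IntegerMatrix sample_configurations_cpp(int mech, double h, int N, double B,
                                        double t, int n, double seed) {
  IntegerMatrix out(n, N);
  uint64_t base = (uint64_t)seed;
  Xoshiro rng(splitmix64(base));
  std::vector<int> place(N), parts(N);
  std::vector<double> wts(N);
  for (int r = 0; r < n; ++r) {
    move_all(rng, mech, h, N, B, t, place, parts, wts);
    for (int i = 0; i < N; ++i) out(r, i) = place[i] + 1;
  }
  return out;
}
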