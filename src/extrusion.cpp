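#include <Rcpp.h>
using namespace Rcpp;

// 1D loop-extrusion kernel with dynamic barriers.
//
// Lattice: nSites consecutive sites; a loop extruder ("LEF", i.e. cohesin)
// occupies two sites (its legs) and translocates them outward one site per
// step. Barriers (CTCF) flip stochastically between bound (blocking) and
// unbound (permissive) states with per-step switch probabilities derived
// from their mean dwell times.
//
// Per-step phase order:
//   (1) barrier state update
//   (2) extruder death (unload); stalled extruders use the stalled lifetime
//   (3) birth: each unloaded extruder loads with prob birthRate at a random
//       free adjacent site pair; a blocked birth is retried next step
//   (4) translocation: each leg steps outward unless paused, blocked by a
//       bound barrier at the target (orientation-respecting), blocked by
//       another leg, or at a lattice end
//
// Uses R's RNG throughout so results are reproducible under set.seed().
//
// orientation codes: 0 = bidirectional, 1 = blocks leftward-moving legs,
// 2 = blocks rightward-moving legs.

// [[Rcpp::export(name = ".simulate_cpp")]]
List simulate_cpp(int nSites,
                  IntegerVector barrierPos,
                  NumericVector occupancy,
                  NumericVector pUnbind,
                  NumericVector pBind,
                  IntegerVector orientation,
                  int nLefs,
                  double pDeath,
                  double pDeathStalled,
                  double birthRate,
                  double pauseRate,
                  int nSteps,
                  int burnInSteps,
                  int stride)
{
    const int nBar = barrierPos.size();
    if (nLefs < 1) stop("need at least one extruder");
    if (2 * nLefs > nSites) stop("lattice too small for the extruder count");

    // site -> barrier index (-1 none); site -> occupying LEF (-1 free)
    std::vector<int> barrierAt(nSites, -1);
    for (int b = 0; b < nBar; ++b) {
        int p = barrierPos[b];
        if (p < 0 || p >= nSites) stop("barrier position outside lattice");
        if (barrierAt[p] != -1) stop("duplicate barrier position");
        barrierAt[p] = b;
    }

    std::vector<char> bound(nBar);
    for (int b = 0; b < nBar; ++b) bound[b] = (unif_rand() < occupancy[b]);

    std::vector<int> occ(nSites, -1);
    std::vector<int> legL(nLefs, -1), legR(nLefs, -1);
    std::vector<char> loaded(nLefs, 0), stallL(nLefs, 0), stallR(nLefs, 0);

    std::vector<double> profile(nSites, 0.0);
    long long nSnapshots = 0, legPairs = 0;

    for (int step = 0; step < nSteps; ++step) {
        // (1) barriers
        for (int b = 0; b < nBar; ++b) {
            if (bound[b]) {
                if (unif_rand() < pUnbind[b]) bound[b] = 0;
            } else {
                if (unif_rand() < pBind[b]) bound[b] = 1;
            }
        }
        // (2) death
        for (int i = 0; i < nLefs; ++i) {
            if (!loaded[i]) continue;
            double p = (stallL[i] || stallR[i]) ? pDeathStalled : pDeath;
            if (p > 0 && unif_rand() < p) {
                occ[legL[i]] = -1;
                occ[legR[i]] = -1;
                loaded[i] = 0;
                stallL[i] = stallR[i] = 0;
            }
        }
        // (3) birth
        for (int i = 0; i < nLefs; ++i) {
            if (loaded[i]) continue;
            if (unif_rand() < birthRate) {
                int s = (int)(unif_rand() * (nSites - 1));
                if (s >= nSites - 1) s = nSites - 2;
                if (occ[s] == -1 && occ[s + 1] == -1) {
                    legL[i] = s;
                    legR[i] = s + 1;
                    occ[s] = i;
                    occ[s + 1] = i;
                    loaded[i] = 1;
                }
            }
        }
        // (4) translocation
        for (int i = 0; i < nLefs; ++i) {
            if (!loaded[i]) continue;
            // left leg moves to smaller indices
            if (pauseRate <= 0 || unif_rand() >= pauseRate) {
                int cur = legL[i];
                if (cur > 0) {
                    int tgt = cur - 1;
                    if (occ[tgt] != -1) {
                        stallL[i] = 1;
                    } else {
                        int b = barrierAt[tgt];
                        if (b >= 0 && bound[b] &&
                            (orientation[b] == 0 || orientation[b] == 1)) {
                            stallL[i] = 1;
                        } else {
                            occ[cur] = -1;
                            occ[tgt] = i;
                            legL[i] = tgt;
                            stallL[i] = 0;
                        }
                    }
                }
            }
            // right leg moves to larger indices
            if (pauseRate <= 0 || unif_rand() >= pauseRate) {
                int cur = legR[i];
                if (cur < nSites - 1) {
                    int tgt = cur + 1;
                    if (occ[tgt] != -1) {
                        stallR[i] = 1;
                    } else {
                        int b = barrierAt[tgt];
                        if (b >= 0 && bound[b] &&
                            (orientation[b] == 0 || orientation[b] == 2)) {
                            stallR[i] = 1;
                        } else {
                            occ[cur] = -1;
                            occ[tgt] = i;
                            legR[i] = tgt;
                            stallR[i] = 0;
                        }
                    }
                }
            }
        }
        // record
        if (step >= burnInSteps && (step - burnInSteps) % stride == 0) {
            ++nSnapshots;
            for (int i = 0; i < nLefs; ++i) {
                if (!loaded[i]) continue;
                profile[legL[i]] += 1.0;
                profile[legR[i]] += 1.0;
                ++legPairs;
            }
        }
    }

    return List::create(_["leg_counts"] = NumericVector(profile.begin(), profile.end()),
                        _["n_snapshots"] = (double)nSnapshots,
                        _["leg_pairs"] = (double)legPairs);
}
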