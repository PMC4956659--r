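#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>

using namespace Rcpp;

// Exhaustive enumeration of the secondary-structure ensemble of one RNA
// sequence under an additive pair-energy model.  Structures are matchings
// over positions with: canonical pairs only, j >= i + 3 (two unpaired bases
// minimum in a hairpin), at most one partner per position, and -- when
// pseudoknots are admitted -- a bipartite crossing graph ("two-page"
// structures: the pair set splits into two mutually non-crossing pages).
//
// The recursion walks positions left to right; at the leftmost undecided
// position it either leaves it unpaired or pairs it with every admissible
// partner.  Bipartiteness is maintained incrementally with a union-find
// (union by size, parity to root, explicit rollback), so non-two-page
// branches are pruned as soon as they arise.  Boltzmann weights are
// accumulated relative to a lower energy bound E0, i.e. exp((E0 - E)/kT),
// so no overflow is possible for any model.

namespace {

struct Dsu {
    std::vector<int> parent, size, parity; // parity relative to parent
    struct Op { int child, root; };
    std::vector<Op> trail;

    void init(int n) {
        parent.resize(n);
        for (int i = 0; i < n; ++i) parent[i] = i;
        size.assign(n, 1);
        parity.assign(n, 0);
        trail.clear();
    }
    // returns root, sets p to parity of x relative to root
    int find(int x, int &p) const {
        p = 0;
        while (parent[x] != x) { p ^= parity[x]; x = parent[x]; }
        return x;
    }
    // merge with constraint parity(a) xor parity(b) == 1; false on conflict
    bool unite_odd(int a, int b) {
        int pa, pb;
        int ra = find(a, pa), rb = find(b, pb);
        if (ra == rb) return (pa ^ pb) == 1;
        if (size[ra] < size[rb]) { std::swap(ra, rb); std::swap(pa, pb); }
        parent[rb] = ra;
        parity[rb] = pa ^ pb ^ 1;
        size[ra] += size[rb];
        trail.push_back({rb, ra});
        return true;
    }
    size_t mark() const { return trail.size(); }
    void rollback(size_t m) {
        while (trail.size() > m) {
            Op op = trail.back(); trail.pop_back();
            size[op.root] -= size[op.child];
            parent[op.child] = op.child;
            parity[op.child] = 0;
        }
    }
};

struct Enumerator {
    int n;
    std::vector<int> base;                  // 0=A,1=C,2=G,3=U
    double e[4][4];                         // pair energies, +inf if disallowed
    bool ok[4][4];
    double q[4][4];                         // exp(-e/kT)
    double kT, pkPenalty, pkFactor, stackE, stackFactor;
    bool pkAllowed, listAll;
    R_xlen_t maxStructures;                 // abort guard; <0 = unlimited

    std::vector<int> partner;               // -2 undecided, -1 unpaired, else idx
    std::vector<std::vector<int>> cand;     // admissible partners j > i
    std::vector<int> pi_, pj_;              // pairs along current path
    Dsu dsu;

    // accumulators
    long double Q = 0.0L;
    R_xlen_t count = 0;
    std::vector<long double> accP, accPn, accPnn; // n*n, row-major
    double mfeE = 0.0;
    std::string mfeDb;
    std::vector<std::string> outDb;
    std::vector<double> outE;

    std::vector<int> page;                  // scratch, per pair slot
    std::vector<signed char> compPar;       // scratch, per pair slot (root)

    void setup() {
        partner.assign(n, -2);
        cand.assign(n, {});
        for (int i = 0; i < n; ++i)
            for (int j = i + 3; j < n; ++j)
                if (ok[base[i]][base[j]]) cand[i].push_back(j);
        dsu.init(n / 2 + 1);
        accP.assign((size_t)n * n, 0.0L);
        accPn.assign((size_t)n * n, 0.0L);
        accPnn.assign((size_t)n * n, 0.0L);
        page.assign(n / 2 + 1, 0);
        compPar.assign(n / 2 + 1, -1);
        mfeDb.assign(n, '.');
        mfeE = 0.0; // open chain
        pkFactor = std::exp(-pkPenalty / kT);
        stackFactor = std::exp(-stackE / kT);
    }

    std::string dotbracket() {
        std::string s(n, '.');
        for (size_t k = 0; k < pi_.size(); ++k) {
            if (page[k] == 1) { s[pi_[k]] = '('; s[pj_[k]] = ')'; }
            else              { s[pi_[k]] = '['; s[pj_[k]] = ']'; }
        }
        return s;
    }

    void leaf(double w, double E) {
        int np = (int)pi_.size();
        // canonical page assignment: within each crossing component the
        // 5'-most pair (lowest slot index: pairs are added with increasing i)
        // is page 1, parity propagates along crossing edges
        int npk = 0;
        for (int k = 0; k < np; ++k) {
            int p; int r = dsu.find(k, p);
            if (compPar[r] < 0) compPar[r] = (signed char)p; // k is 5'-most
            page[k] = (p == compPar[r]) ? 1 : 2;
            if (page[k] == 2) ++npk;
        }
        for (int k = 0; k < np; ++k) { int p; compPar[dsu.find(k, p)] = -1; }

        double wl = w, El = E;
        if (npk) { wl *= std::pow(pkFactor, npk); El += pkPenalty * npk; }
        Q += wl;
        ++count;
        for (int k = 0; k < np; ++k) {
            size_t idx = (size_t)pi_[k] * n + pj_[k];
            accP[idx] += wl;
            (page[k] == 1 ? accPn : accPnn)[idx] += wl;
        }
        if (count == 1 || El < mfeE - 1e-9) {
            mfeE = El; mfeDb = dotbracket();
        } else if (El < mfeE + 1e-9) {
            std::string db = dotbracket();
            if (db < mfeDb) { mfeE = std::min(mfeE, El); mfeDb = db; }
        }
        if (listAll) { outDb.push_back(dotbracket()); outE.push_back(El); }
        if (maxStructures >= 0 && count > maxStructures)
            stop("ensemble larger than maxStructures guard (%d)",
                 (int)maxStructures);
    }

    void rec(int i, double w, double E) {
        while (i < n && partner[i] != -2) ++i;
        if (i == n) { leaf(w, E); return; }
        // option 1: leave i unpaired
        partner[i] = -1;
        rec(i + 1, w, E);
        partner[i] = -2;
        // option 2: pair i with each admissible j
        int slot = (int)pi_.size();
        for (int j : cand[i]) {
            if (partner[j] != -2) continue;
            size_t m = dsu.mark();
            bool feasible = true;
            // existing pairs all start left of i; (k,l) crosses (i,j) iff i<l<j
            for (int s = 0; s < slot && feasible; ++s) {
                if (pi_[s] < i && pj_[s] > i && pj_[s] < j) {
                    if (!pkAllowed) { feasible = false; break; }
                    feasible = dsu.unite_odd(slot, s);
                }
            }
            if (!feasible) { dsu.rollback(m); continue; }
            partner[i] = j; partner[j] = i;
            pi_.push_back(i); pj_.push_back(j);
            // helix stacking: (i-1, j+1) already decided earlier in the scan
            bool stacked = (i > 0 && j + 1 < n && partner[i - 1] == j + 1);
            double wf = q[base[i]][base[j]] * (stacked ? stackFactor : 1.0);
            double ef = e[base[i]][base[j]] + (stacked ? stackE : 0.0);
            rec(i + 1, w * wf, E + ef);
            pi_.pop_back(); pj_.pop_back();
            partner[i] = -2; partner[j] = -2;
            dsu.rollback(m);
        }
    }
};

int baseCode(char c) {
    switch (c) {
        case 'A': return 0; case 'C': return 1;
        case 'G': return 2; case 'U': return 3;
    }
    stop("invalid RNA base '%c'", c);
    return -1;
}

} // namespace

// [[Rcpp::export(name = ".Call_enumerate")]]
List enumerate_cpp(std::string seq, NumericVector pairEnergy, double pkPenalty,
                   double stackEnergy, double thermalEnergy, bool pkAllowed,
                   bool listStructures, double maxStructures) {
    Enumerator en;
    en.n = (int)seq.size();
    en.base.resize(en.n);
    for (int i = 0; i < en.n; ++i) en.base[i] = baseCode(seq[i]);

    // pairEnergy named AU, GC, GU (unordered classes)
    double eAU = pairEnergy["AU"], eGC = pairEnergy["GC"], eGU = pairEnergy["GU"];
    for (int a = 0; a < 4; ++a)
        for (int b = 0; b < 4; ++b) { en.ok[a][b] = false; en.e[a][b] = R_PosInf; }
    auto setPair = [&](int a, int b, double v) {
        en.ok[a][b] = en.ok[b][a] = true;
        en.e[a][b] = en.e[b][a] = v;
    };
    setPair(0, 3, eAU); // A-U
    setPair(2, 1, eGC); // G-C
    setPair(2, 3, eGU); // G-U
    en.kT = thermalEnergy;
    en.pkPenalty = pkPenalty;
    en.stackE = stackEnergy;
    en.pkAllowed = pkAllowed;
    en.listAll = listStructures;
    en.maxStructures = maxStructures < 0 ? -1 : (R_xlen_t)maxStructures;
    for (int a = 0; a < 4; ++a)
        for (int b = 0; b < 4; ++b)
            en.q[a][b] = en.ok[a][b] ? std::exp(-en.e[a][b] / en.kT) : 0.0;

    // Guard against weight overflow: the most favourable structure has at
    // most n/2 pairs at the best pair energy (plus any negative pk penalty).
    // Its Boltzmann factor must stay below double overflow for unshifted
    // accumulation to be exact; at enumerable lengths this is ample room.
    double emin = std::min(std::min(eAU, eGC), std::min(eGU, 0.0)) +
                  std::min(pkPenalty, 0.0) + std::min(stackEnergy, 0.0);
    if (-(en.n / 2) * emin / thermalEnergy > 600.0)
        stop("energy model too favourable for exact accumulation at this length");

    en.setup();
    en.rec(0, 1.0, 0.0);

    int n = en.n;
    NumericMatrix P(n, n + 1), Pn(n, n), Pnn(n, n);
    long double Q = en.Q;
    for (int i = 0; i < n; ++i) {
        long double rowsum = 0.0L;
        for (int j = 0; j < n; ++j) {
            long double pij = en.accP[(size_t)i * n + j] + en.accP[(size_t)j * n + i];
            P(i, j) = (double)(pij / Q);
            Pn(i, j) = (double)((en.accPn[(size_t)i * n + j] +
                                 en.accPn[(size_t)j * n + i]) / Q);
            Pnn(i, j) = (double)((en.accPnn[(size_t)i * n + j] +
                                  en.accPnn[(size_t)j * n + i]) / Q);
            rowsum += pij / Q;
        }
        // unpaired probability by the row-sum law (guard tiny negative fuzz)
        P(i, n) = std::max(0.0, (double)(1.0L - rowsum));
    }

    List out = List::create(
        _["Q"] = (double)Q,
        _["logQ"] = (double)std::log(Q),
        _["numStructures"] = (double)en.count,
        _["P"] = P, _["Pnested"] = Pn, _["Pnonnested"] = Pnn,
        _["mfeDotbracket"] = en.mfeDb,
        _["mfeEnergy"] = en.mfeE);
    if (listStructures) {
        int m = (int)en.outDb.size();
        CharacterVector db(m);
        NumericVector ee(m), pp(m);
        for (int k = 0; k < m; ++k) {
            db[k] = en.outDb[k];
            ee[k] = en.outE[k];
            pp[k] = (double)(std::exp(-en.outE[k] / en.kT) / (double)Q);
        }
        out["structures"] = db;
        out["energies"] = ee;
        out["probabilities"] = pp;
    }
    return out;
}
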