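#include <Rcpp.h>
using namespace Rcpp;

// log((1 + e^theta * x)/(1 + x)) with x given as log(x); logx = -Inf means x = 0.
static inline double log_factor(double theta, double logx) {
    if (logx == R_NegInf) return 0.0;
    double a = theta + logx;
    double la = (a > 35.0) ? a + log1p(std::exp(-a)) : log1p(std::exp(a));
    double lb = (logx > 35.0) ? logx + log1p(std::exp(-logx)) : log1p(std::exp(logx));
    return la - lb;
}

static inline double stim_value(const double* s, double t) {
    // s = {rampUpStart, rampUpEnd, plateauEnd, rampDownEnd, amplitude}
    if (t <= s[0] || t >= s[3]) return 0.0;
    if (t < s[1]) return s[4] * (t - s[0]) / (s[1] - s[0]);
    if (t <= s[2]) return s[4];
    return s[4] * (s[3] - t) / (s[3] - s[2]);
}

// Simulate one cell of the piecewise-deterministic promoter/mRNA/protein
// process with discrete-time Bernoulli promoter updates and exact
// (closed-form) mRNA/protein integration within each step.
//
// theta, H: (nGenes + nStim) x nGenes, gene regulator rows first.
// stim: nStim x 5 schedule matrix (see stim_value).
// Uses R's RNG stream: one uniform per gene per step, genes in order.
// [[Rcpp::export(name = ".pdmpCellCpp")]]
List pdmp_cell_cpp(NumericVector s0, NumericVector d0, NumericVector s1,
                   NumericVector d1, NumericVector konMin, NumericVector konMax,
                   NumericVector koffMin, NumericVector koffMax,
                   NumericVector logBetaOn, NumericVector logBetaOff,
                   NumericVector logPhiRefOn, NumericVector logPhiRefOff,
                   NumericMatrix theta, NumericMatrix H, double gamma,
                   NumericVector pScale, NumericMatrix stim,
                   double burnIn, double postStimulus, double dt,
                   double sampleEvery,
                   IntegerVector E0, NumericVector M0, NumericVector P0,
                   bool applyStimuli) {
    const int nG = s0.size();
    const int nS = stim.nrow();
    const int stepsPerSample = (int) std::lround(sampleEvery / dt);
    const int nSteps = (int) std::lround((burnIn + postStimulus) / dt);
    const int nSamples = nSteps / stepsPerSample + 1;

    std::vector<double> logH((nG + nS) * nG), thetav((nG + nS) * nG);
    for (int w = 0; w < nG + nS; ++w)
        for (int i = 0; i < nG; ++i) {
            logH[w * nG + i] = std::log(H(w, i));
            thetav[w * nG + i] = theta(w, i);
        }

    NumericMatrix Msamp(nSamples, nG), Psamp(nSamples, nG);
    IntegerMatrix Esamp(nSamples, nG);
    NumericVector times(nSamples);

    std::vector<int> E(E0.begin(), E0.end());
    std::vector<double> M(M0.begin(), M0.end()), P(P0.begin(), P0.end());
    std::vector<double> logxg(nG);  // log((P_j/pScale_j / H)^gamma) pieces
    std::vector<double> q(nS);

    RNGScope scope;

    int isamp = 0;
    double t = -burnIn;
    times[0] = t;
    for (int i = 0; i < nG; ++i) {
        Msamp(0, i) = M[i]; Psamp(0, i) = P[i]; Esamp(0, i) = E[i];
    }
    for (int step = 1; step <= nSteps; ++step) {
        // stimulus intensities frozen at step start
        for (int s = 0; s < nS; ++s) {
            double v = 0.0;
            if (applyStimuli) {
                double row[5] = {stim(s, 0), stim(s, 1), stim(s, 2),
                                 stim(s, 3), stim(s, 4)};
                v = stim_value(row, t);
            }
            q[s] = v;
        }
        // normalized protein log-levels
        std::vector<double> logp(nG);
        for (int j = 0; j < nG; ++j) {
            double pn = P[j] / pScale[j];
            logp[j] = (pn > 0.0) ? std::log(pn) : R_NegInf;
        }
        // promoter update per gene (rates frozen over the step)
        for (int i = 0; i < nG; ++i) {
            double lpOn = 0.0, lpOff = 0.0;
            for (int s = 0; s < nS; ++s) {
                double th = thetav[(nG + s) * nG + i];
                if (th == 0.0 || q[s] == 0.0) continue;  // factor is exactly 1
                double lx = std::log(q[s]) - logH[(nG + s) * nG + i];
                lpOn += log_factor(th, lx);
                lpOff += log_factor(-th, lx);
            }
            for (int j = 0; j < nG; ++j) {
                double th = thetav[j * nG + i];
                if (th == 0.0 || logp[j] == R_NegInf) continue;
                double lx = gamma * (logp[j] - logH[j * nG + i]);
                lpOn += log_factor(th, lx);
                lpOff += log_factor(-th, lx);
            }
            double sOn = logBetaOn[i] + lpOn - logPhiRefOn[i];
            double sOff = logBetaOff[i] + lpOff - logPhiRefOff[i];
            double kon = konMin[i] + konMax[i] / (1.0 + std::exp(-sOn));
            double koff = koffMin[i] + koffMax[i] / (1.0 + std::exp(-sOff));
            double ksum = kon + koff;
            double ee = std::exp(-dt * ksum);
            double pi = E[i] * ee + (kon / ksum) * (1.0 - ee);
            double u = R::unif_rand();
            int Enew = (u < pi) ? 1 : 0;
            // exact linear update with the NEW promoter state held constant
            double C = s0[i] * Enew / d0[i];
            double A = M[i] - C;
            double em0 = std::exp(-d0[i] * dt);
            double em1 = std::exp(-d1[i] * dt);
            double Mnew = C + A * em0;
            double conv;
            double dd = d1[i] - d0[i];
            if (std::fabs(dd) < 1e-9 * std::max(d0[i], d1[i]))
                conv = dt * em0;                       // analytic d0 == d1 limit
            else
                conv = (em0 - em1) / dd;
            double Pnew = P[i] * em1 +
                s1[i] * (A * conv + C * (1.0 - em1) / d1[i]);
            E[i] = Enew;
            M[i] = (Mnew > 0.0) ? Mnew : 0.0;
            P[i] = (Pnew > 0.0) ? Pnew : 0.0;
        }
        t = -burnIn + step * dt;
        if (step % stepsPerSample == 0) {
            ++isamp;
            times[isamp] = t;
            for (int i = 0; i < nG; ++i) {
                Msamp(isamp, i) = M[i];
                Psamp(isamp, i) = P[i];
                Esamp(isamp, i) = E[i];
            }
        }
    }
    return List::create(_["times"] = times, _["M"] = Msamp, _["P"] = Psamp,
                        _["E"] = Esamp);
}
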