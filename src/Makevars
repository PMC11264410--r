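# The environment Makeconf appends CXXFLAGS (-O2 -march=nocona) last, so
# override it here: the engine is hot scalar floating-point code and gains
# substantially from full optimization on the build host ISA.
CXXFLAGS = -O3 -march=native -fno-math-errno -funroll-loops
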